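---
title: "Methods: models, numerics and design choices in magnetherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics and design choices in magnetherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetherm)
```

`magnetherm` simulates magnetic nanoparticle hyperthermia of a skin tumor:
a gold-coated magnetite ferrofluid heats under an AC field, the heat
diffuses through perfused tissue, and thermal damage accumulates. This
vignette records the models, their assumptions, the numerical choices, and
the places where the design was genuinely open — including the parameter
ambiguities that make some headline values of the underlying study
irreproducible from its own tables.

## Ferrofluid composition

Spectroscopy (DCP-AES) reports two atom-count ratios against gold:
N~Fe(T)~/N~Au~ = 56/44 over all particles and N~Fe(C)~/N~Au~ = 47/53 over
the coated ones. Since the batch is treated as monodisperse, the uncoated
particle fraction is `1 − r_coated/r_total` ≈ 30.3 %. A magnetite formula
unit carries three iron atoms, so the per-formula gold ratio is
AR = 1/(3 r~coated~) = 53/141. Equating AR with the mass/molar-mass ratio
of a spherical core-shell particle and inverting gives the shell
thickness:

$$d_\mathrm{shell} = \frac{D_\mathrm{core}}{2}\left[\sqrt[3]{1 +
  3\,\mathrm{AR}\,\frac{\rho_\mathrm{core}}{\rho_\mathrm{shell}}
  \frac{M_\mathrm{shell}}{M_\mathrm{core}}} - 1\right]
  \approx 0.55\ \mathrm{nm}$$

for D~core~ = 13.90 nm, densities 5.196/19.3 g/cm³ and molar masses
231.5326/196.9666 g/mol. Constructors accept nm and g/cm³ and convert to
SI once at the boundary; the inversion and its forward form
(`atomic_ratio_from_geometry()`) are exact inverses, tested to 1e-12
relative over AR ∈ (0, 10].

Note a factor-of-ten tension in the source material: the particle table
lists d~shell~ = 5.5 nm while the composition inversion yields 0.55 nm.
Both are representable; the heating defaults use the tabled 5.5 nm (it
sets the hydrodynamic volume and hence the Brownian time), and the
composition module derives 0.55 nm from the ratios.

## Linear-response heating

The volumetric power of the suspension follows Rosensweig's linear
response theory:

$$Q_\mathrm{nano} = \pi\mu_0\chi_0 H_0^2 f\,
  \frac{2\pi f\tau_\mathrm{eff}}{1+(2\pi f\tau_\mathrm{eff})^2},\qquad
  \frac{1}{\tau_\mathrm{eff}} = \frac{1}{\tau_N} + \frac{1}{\tau_B}$$

with the Néel time (√π/2)·τ₀·e^Γ/√Γ, Γ = KV~m~/k~B~T, the Brownian time
3ηV~h~/k~B~T, and the equilibrium susceptibility given by the Langevin
chord χ₀ = χ~i~(3/ξ)(coth ξ − 1/ξ). Assumptions inherited from the theory:
monodisperse non-interacting particles, field amplitude small enough that
the linear (chord) susceptibility applies, and relaxation times evaluated
at a fixed reference temperature (default 310.15 K) — the power is a
*constant* source, not re-evaluated against the evolving tissue field.

Numerical choices:

* The chord factor is evaluated by its series 1 − ξ²/15 + 2ξ⁴/315 below
  ξ = 0.01 and directly above. At the switchover both branches agree to
  ~1e-12; placing the switchover lower (e.g. 1e-4) would leave the direct
  branch with ~1e-8 cancellation error from coth ξ − 1/ξ.
* For Γ > 700, exp(Γ) overflows double precision; `neel_time()` returns
  `Inf` with a `neel_blocked` flag and the chain degrades gracefully to
  Brownian-only relaxation.
* With τ~eff~ independent of frequency, Q rises monotonically in f and
  saturates at πμ₀χ₀H₀²/(2πτ~eff~); only the Debye factor
  x/(1+x²) is unimodal, peaking at exactly ½ when 2πfτ~eff~ = 1. The tests
  assert this saturating form and the analytic asymptote.

Two tabled inputs are mutually inconsistent with the headline power
Q~nano~ = 214 kW/m³: with the tabled volume fraction φ = 0.071 the chain
yields ≈ 25 kW/m³, while the chord reading φ = M~s~/M~d~ ≈ 0.698
(`phi_saturation()`) yields ≈ 244 kW/m³ — within a factor 1.5 of the
headline, and the only reading that approaches it. Which set produced
214 kW/m³ is not recoverable; therefore the bioheat stage accepts
`Q_nano` as a direct input (default 214 kW/m³) rather than coupling it to
this module. Likewise the tabled H₀ = 1500 A/m and the simulated coil
center 750 A/m are both accepted as explicit configuration.

## Coil field

The excitation coil (3 turns, 15 A, radius 30 mm, length 40 mm, symmetric
half-lengths a = b = l/2 — the only reading consistent with a coil
centered on the tumor) has the closed-form on-axis current-sheet field
implemented in `on_axis_flux_density()`. The independent check is
`loop_superposition_field()`: N discrete loops at
z = −l/2 + (k+½)l/N, preserving total ampere-turns and symmetry, each an
exact complete-elliptic-integral single-loop solution (via
`pracma::ellipke`). The two routes agree on-axis to < 2 % for the physical
3-loop winding and < 0.2 % for ≥ 20 loops (the sheet limit). Evaluation on
a winding centerline is singular and rejected. The coil field is *not*
coupled into the bioheat solve — the tumor source is the prescribed
Q~nano~ — so this module is a verification surface. The study's three
reported field numbers (analytic peak 0.32 mT, FEM center 0.7 mT,
H₀ = 750 A/m) are mutually inconsistent under the sheet formula with the
stated coil, so none is used as a hard target.

## Bioheat solve

The Pennes equation is solved on the nested-cylinder geometry: tumor
radius 5 mm inside skin radius 15 mm, common height 30 mm. The study
solved 3-D FEM; this package solves the axisymmetric (r, z) reduction,
which is *exact* for coaxial cylinders with axisymmetric sources — the
same physics at desk-scale runtime, with no angular discretization
ambiguity.

Discretization and defaults:

* Cell-centered finite volumes, dr = dz = 0.5 mm by default (10 radial
  cells across the tumor). Cell volumes 2πr·dr·dz integrate the cylinder
  volumes exactly.
* Face conductivities are harmonic means, the standard choice that keeps
  flux continuous across the tumor–skin property jump. The r = 0 axis is a
  natural symmetry boundary.
* Boundary conditions: the lateral surface r = 15 mm carries the Robin
  condition with h = 3.6 W/m²/K and T~ext~ = 37 °C; the z faces are
  insulated. The source text says both "convective heat flux at the skin
  surface" and "thermal insulation at the outer boundaries"; the face
  assignment is configurable (`convective_faces`), and at h = 3.6 W/m²/K
  the distinction moves the peak by millikelvins.
* Tissue properties are the tabled ones (tumor = muscle-equivalent:
  ρ 1090, C~p~ 3421, k 0.563, ω~b~ 1.34e-2 1/s, Q~met~ 13.08 kW/m³; skin:
  ρ 1109, C~p~ 3391, k 0.37, ω~b~ 1.96e-3 1/s, Q~met~ 1.83 kW/m³). The
  table's tumor Q~met~ = 13.08 kW/m³ is taken as authoritative over the
  conflicting in-text 1.83 kW/m³; both are one-argument changes. Perfusion
  and metabolism are assigned per cell by nearest material.
* Time integration is theta-implicit with the operator assembled and
  Cholesky-factorized once: backward Euler (dt = 1 s default,
  unconditionally stable, first order — ample since the solution is near
  steady state well before 60 min) or Crank–Nicolson for second-order
  accuracy where trajectories matter (the relaxation verification uses it).
* Temperatures are kelvin internally; `tidy()`/`glance()` and the plot
  functions convert to Celsius at the I/O boundary.
* Every step checks a discrete energy-balance residual (stored heat minus
  net sources, relative to the source magnitude); a residual above 1e-8
  surfaces as a hard error. In practice it sits at ~1e-13.

Verification, all run in the test suite: a uniform blood-temperature state
is a fixed point to 1e-12 K; uniform perfusion-only cooling matches the
ODE closed form T~b~ + (T₀−T~b~)e^(−t/τ), τ = ρC~p~/(ρ~b~C~b~ω~b~) ≈
73.3 s, to 1e-4 relative; halving dt moves the 60-min solution < 1e-3 K;
refining 0.5 mm → 0.25 mm moves the peak ≈ 1e-3 K (< 0.05 K); and the peak
always stays below the perfusion-dominated bound
T~b~ + (Q~nano~+Q~met~)/(ρ~b~C~b~ω~b~).

**The 42.3 °C headline.** With the tabled parameters and Q~nano~ =
214 kW/m³, the perfusion bound is 37 + 4.46 = 41.46 °C, and the full solve
lands at ≈ 40.4 °C (conduction drains the 5 mm tumor, whose radius is only
~1.5 perfusion length scales). The study reports 42.3 °C, which exceeds
even the conduction-free bound of its own parameters; reproducing it would
need ~60 % more source power or ~40 % less tumor perfusion, or the
nonuniform (Gaussian) particle concentration the study narrates but does
not parameterize. The package reports what the stated parameters yield.

Probes default to six points P1…P6 equally spaced along the mid-height
radius (the study never gives their coordinates numerically; mid-height is
the natural symmetry plane). Probe extraction is bilinear in the stored
fields with constant extrapolation beyond the outermost cell centers —
second-order correct at the axis where ∂T/∂r = 0.

## Arrhenius damage

Damage is post-processing on stored histories:
Ω = ∫A~f~ exp(−E~a~/RT)dt by trapezoid (exact for constant temperature,
second-order for smooth profiles, additive over windows split at stored
samples), and θ = 1 − exp(−Ω). Two sign/magnitude corrections were
unavoidable: the printed necrosis formula 1 − exp(+Ω) yields negative
fractions, so the standard 1 − exp(−Ω) is implemented; and the printed
activation energy 6.27e8 J/mol makes the damage rate identically zero at
any attainable temperature (e^(−238000)), so the default is the
Henriques-type 6.27e5 J/mol consistent with A~f~ = 3.1e98 1/s, with the
printed value available by configuration. Even so, one hour at 43 °C
yields Ω ≈ 0.03 (θ ≈ 3 %): the study's "90–99 % damage" is not
reproducible from its printed kinetics and 42.3 °C peak under any standard
reading, and is treated as qualitative. The damage stage is therefore
verified by properties (closed form, additivity, monotonicity, θ ∈ [0,1))
rather than against that figure. Field damage integrates the stored
60-second field cadence, adequate because temperatures plateau within the
first few minutes.

## Sensitivity sweeps

`run_sweep()` re-solves the full transient problem per value of one
parameter over the printed grids (ω~b~ 0.001–0.005 1/s, ρ~b~ 700–1100
kg/m³, C~b~ 2800–4400 J/kg/K, Q~met~ 1–5 kW/m³, Q~nano~ 110–190 kW/m³).
Whether the study varied tumor-only or both-tissue values is unstated;
perfusion and metabolic sweeps here alter both tissue domains (blood
properties are global by construction, Q~nano~ is the tumor source). The
headline scalar is the domain-maximum temperature at 60 min — robust to
the probe-placement ambiguity. Runs share no mutable state, so results
are order-independent, and a failing run reports in its row without
aborting the sweep. All five qualitative directions reproduce: inverse
for ω~b~, ρ~b~, C~b~; direct for Q~met~, Q~nano~. The acceptance suite
runs the sweeps on a 1 mm / 5 s grid; the directions are grid-robust
because they reflect the sign structure of the perfusion balance, not
discretization detail.

## Scenario generation and synthetic data

`default_scenario()` emits the study's base configuration; JSON
round-trips are lossless and validated through the constructors on read.
Ensembles draw parameters uniformly within the printed sweep ranges from
a single seeded private stream (`withr::with_seed`) — uniform rather than
Latin-hypercube sampling, the simplest defensible default for
single-parameter sensitivity screening, and the study prescribes only
fixed grids. Synthetic temperature histories (constant, ramp,
ramp-plateau, noisy plateau) exercise the damage stage without a PDE
solve; the constant kind enables the exact closed-form oracle. What the
generator does *not* emulate: spatially varying particle concentration,
temperature-dependent material properties, vascular geometry, or
measurement noise in real thermometry — passing tests demonstrate
correctness of the stated model, not fidelity to clinical data.

## Problem sizes used in the checks

The verification suite runs transient solves on the 1 mm / 5 s grid
(15 × 30 cells, 720 steps) where grid detail is immaterial, and the
full-resolution 0.5 mm / 1 s solve (30 × 60 cells, 3600 steps, ~3 s of
compute) plus one 0.25 mm refinement for the headline temperature and
convergence checks. These sizes fully resolve the 3.3 mm perfusion length
scale of the tumor.

## Known limitations

* No particle transport: Q~nano~ is uniform in the tumor, as in the
  parameterized model of the study (its diffusion discussion is
  narrative only).
* No temperature feedback on material properties or on the LRT chain.
* No vascular network; perfusion is the distributed Pennes sink.
* Strictly linear response: no hysteresis or Stoner–Wohlfarth dynamics,
  no particle-size distribution averaging.
* The electromagnetic solve is the analytic/loop-sum coil field only; no
  eddy currents or tissue electrical properties.

```{r example, eval = FALSE}
library(magnetherm)
sc <- default_scenario()
hist <- simulate_bioheat(sc$model, sc$grid)
glance(hist)            # peak ~40.4 C, bound 41.46 C
autoplot(hist)          # probe traces
damage_summary(damage_integral(hist))
monotonicity_report(run_sweep(sweep_spec("omega_b")))
```
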