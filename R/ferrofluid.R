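#' Atomic-ratio specification of a gold-coated magnetite ferrofluid
#'
#' DCP-AES (direct current plasma atomic emission spectroscopy) measurements
#' of a mixed ferrofluid are reported as two atom-count ratios against gold:
#' `r_total`, the ratio of all iron atoms (coated plus uncoated particles) to
#' gold atoms, and `r_coated`, the ratio of iron atoms residing in gold-coated
#' particles to gold atoms. Defaults are the measured values 56/44 and 47/53.
#'
#' @param r_total Ratio of total iron atoms to gold atoms (dimensionless, > 0).
#' @param r_coated Ratio of iron atoms in coated particles to gold atoms
#'   (dimensionless, > 0, and at most `r_total`).
#' @return A list of class `atom_ratio_spec`.
#' @examples
#' atom_ratio_spec()
#' @export
atom_ratio_spec <- function(r_total = 56 / 44, r_coated = 47 / 53) {
  check_number(r_total, "r_total", min = 0, strict_min = TRUE)
  check_number(r_coated, "r_coated", min = 0, strict_min = TRUE)
  if (r_coated > r_total) {
    abort(paste0(
      "Invalid atomic ratios: `r_coated` (", format(r_coated),
      ") exceeds `r_total` (", format(r_total),
      "); the uncoated particle fraction would be negative."
    ))
  }
  structure(list(r_total = r_total, r_coated = r_coated),
            class = "atom_ratio_spec")
}

#' Core-shell nanoparticle geometry and materials
#'
#' Describes one monodisperse population of spherical core-shell particles:
#' a magnetite core of diameter `d_core` wrapped in a gold shell of thickness
#' `d_shell`. Lengths are accepted in nanometres and densities in g/cm^3 (the
#' units materials tables print) and converted to SI once, here, so all
#' downstream arithmetic is unit-consistent.
#'
#' @param d_core Core diameter in nm (> 0). Default 13.90 nm, the DCP-AES
#'   estimate for the magnetite core.
#' @param d_shell Shell thickness in nm (>= 0). Default 0.55 nm, the value the
#'   composition inversion yields from the measured atomic ratio.
#' @param rho_core,rho_shell Mass densities in g/cm^3 (> 0). Defaults: 5.196
#'   (magnetite) and 19.3 (gold).
#' @param molar_core,molar_shell Molar masses in g/mol (> 0). Defaults:
#'   231.5326 (Fe3O4) and 196.9666 (Au).
#' @return A list of class `core_shell_geometry` with SI fields:
#'   `d_core`, `d_shell` (m), `rho_core`, `rho_shell` (kg/m^3),
#'   `molar_core`, `molar_shell` (kg/mol).
#' @examples
#' geom <- core_shell_geometry()
#' core_mass(geom)
#' @export
core_shell_geometry <- function(d_core = 13.90, d_shell = 0.55,
                                rho_core = 5.196, rho_shell = 19.3,
                                molar_core = 231.5326,
                                molar_shell = 196.9666) {
  check_number(d_core, "d_core", min = 0, strict_min = TRUE)
  check_number(d_shell, "d_shell", min = 0)
  check_number(rho_core, "rho_core", min = 0, strict_min = TRUE)
  check_number(rho_shell, "rho_shell", min = 0, strict_min = TRUE)
  check_number(molar_core, "molar_core", min = 0, strict_min = TRUE)
  check_number(molar_shell, "molar_shell", min = 0, strict_min = TRUE)
  structure(list(
    d_core = d_core * 1e-9,          # nm -> m
    d_shell = d_shell * 1e-9,
    rho_core = rho_core * 1e3,       # g/cm^3 -> kg/m^3
    rho_shell = rho_shell * 1e3,
    molar_core = molar_core * 1e-3,  # g/mol -> kg/mol
    molar_shell = molar_shell * 1e-3
  ), class = "core_shell_geometry")
}

#' Fraction of uncoated magnetite particles in the ferrofluid
#'
#' The synthesis leaves a fraction of magnetite cores without a gold shell.
#' Since every particle of a monodisperse batch carries the same number of
#' iron atoms, the uncoated atom fraction equals the uncoated particle
#' fraction: `1 - r_coated / r_total`.
#'
#' @param ratios An [atom_ratio_spec()].
#' @return Dimensionless fraction in \[0, 1\].
#' @examples
#' uncoated_fraction(atom_ratio_spec()) # ~0.303 for the measured ratios
#' @export
uncoated_fraction <- function(ratios = atom_ratio_spec()) {
  stopifnot(inherits(ratios, "atom_ratio_spec"))
  1 - ratios$r_coated / ratios$r_total
}

#' Gold-to-iron atomic ratio of the coated particles
#'
#' A magnetite formula unit Fe3O4 carries three iron atoms, so the per-formula
#' gold-to-iron-oxide atomic ratio is `AR = N_Au / (3 N_Fe(C)) =
#' 1 / (3 r_coated)`.
#'
#' @param r_coated Iron(coated)-to-gold atom ratio (> 0), or an
#'   [atom_ratio_spec()] whose `r_coated` field is used.
#' @return Dimensionless atomic ratio AR.
#' @examples
#' gold_iron_ratio(47 / 53) # 53/141 ~ 0.3759
#' @export
gold_iron_ratio <- function(r_coated = 47 / 53) {
  if (inherits(r_coated, "atom_ratio_spec")) r_coated <- r_coated$r_coated
  check_number(r_coated, "r_coated", min = 0, strict_min = TRUE)
  1 / (3 * r_coated)
}

#' Gold-to-iron-oxide atomic ratio from component masses
#'
#' Mass/molar-mass form of the same atomic ratio computed by
#' [gold_iron_ratio()]: `AR = (m_shell / M_shell) / (3 m_core / M_core)`.
#' Exposed separately so the atom-count and mass-based routes can be checked
#' against each other.
#'
#' @param m_core,m_shell Component masses (kg, > 0 core, >= 0 shell).
#' @param geom A [core_shell_geometry()] supplying the molar masses.
#' @return Dimensionless atomic ratio AR.
#' @export
gold_iron_ratio_from_masses <- function(m_core, m_shell,
                                        geom = core_shell_geometry()) {
  stopifnot(inherits(geom, "core_shell_geometry"))
  check_number(m_core, "m_core", min = 0, strict_min = TRUE)
  check_number(m_shell, "m_shell", min = 0)
  (m_shell / geom$molar_shell) / (3 * m_core / geom$molar_core)
}

#' Mass of the magnetite core
#'
#' `(pi/6) d_core^3 rho_core` for a spherical core.
#'
#' @param geom A [core_shell_geometry()].
#' @return Mass in kg.
#' @export
core_mass <- function(geom = core_shell_geometry()) {
  stopifnot(inherits(geom, "core_shell_geometry"))
  pi / 6 * geom$d_core^3 * geom$rho_core
}

#' Mass of the gold shell
#'
#' Spherical-shell volume times gold density:
#' `(pi/6) ((d_core + 2 d_shell)^3 - d_core^3) rho_shell`.
#'
#' @param geom A [core_shell_geometry()].
#' @return Mass in kg.
#' @export
shell_mass <- function(geom = core_shell_geometry()) {
  stopifnot(inherits(geom, "core_shell_geometry"))
  pi / 6 * ((geom$d_core + 2 * geom$d_shell)^3 - geom$d_core^3) *
    geom$rho_shell
}

#' Gold-shell thickness from the atomic ratio
#'
#' Inverts the core-shell mass balance for the shell thickness:
#' \deqn{d_{shell} = \frac{D_{core}}{2}\left[\sqrt[3]{1 + 3\,AR\,
#'   \frac{\rho_{core}}{\rho_{shell}}\frac{M_{shell}}{M_{core}}} - 1\right]}
#' Feeding the result back through [atomic_ratio_from_geometry()] recovers
#' `AR` exactly (round-trip identity used in the tests).
#'
#' @param ar Gold-to-iron-oxide atomic ratio (>= 0).
#' @param geom A [core_shell_geometry()]; its `d_shell` field is ignored.
#' @return Shell thickness in nm.
#' @examples
#' shell_thickness(gold_iron_ratio(47 / 53)) # ~0.55 nm
#' @export
shell_thickness <- function(ar, geom = core_shell_geometry()) {
  stopifnot(inherits(geom, "core_shell_geometry"))
  check_number(ar, "ar", min = 0)
  d <- geom$d_core / 2 *
    ((1 + 3 * ar * (geom$rho_core / geom$rho_shell) *
        (geom$molar_shell / geom$molar_core))^(1 / 3) - 1)
  d * 1e9
}

#' Atomic ratio implied by a core-shell geometry
#'
#' Forward form of the mass balance inverted by [shell_thickness()]:
#' the gold-to-iron-oxide atomic ratio implied by the configured core
#' diameter and shell thickness.
#'
#' @param geom A [core_shell_geometry()].
#' @return Dimensionless atomic ratio AR.
#' @export
atomic_ratio_from_geometry <- function(geom = core_shell_geometry()) {
  stopifnot(inherits(geom, "core_shell_geometry"))
  gold_iron_ratio_from_masses(core_mass(geom), shell_mass(geom), geom)
}

#' Full ferrofluid composition summary
#'
#' Chains the composition operations into one tidy row: uncoated particle
#' fraction, gold-to-iron atomic ratio, derived shell thickness, and the
#' core/shell masses of a single particle at that derived thickness.
#'
#' @param ratios An [atom_ratio_spec()].
#' @param geom A [core_shell_geometry()]; its `d_shell` is replaced by the
#'   value derived from `ratios`.
#' @return A one-row tibble with columns `uncoated_fraction`, `atomic_ratio`,
#'   `d_shell_nm`, `core_mass_kg`, `shell_mass_kg`.
#' @examples
#' ferrofluid_composition()
#' @export
ferrofluid_composition <- function(ratios = atom_ratio_spec(),
                                   geom = core_shell_geometry()) {
  ar <- gold_iron_ratio(ratios)
  d_shell_nm <- shell_thickness(ar, geom)
  geom_derived <- core_shell_geometry(
    d_core = geom$d_core * 1e9, d_shell = d_shell_nm,
    rho_core = geom$rho_core * 1e-3, rho_shell = geom$rho_shell * 1e-3,
    molar_core = geom$molar_core * 1e3, molar_shell = geom$molar_shell * 1e3
  )
  tibble::tibble(
    uncoated_fraction = uncoated_fraction(ratios),
    atomic_ratio = ar,
    d_shell_nm = d_shell_nm,
    core_mass_kg = core_mass(geom_derived),
    shell_mass_kg = shell_mass(geom_derived)
  )
}
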