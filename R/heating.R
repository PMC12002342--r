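#' Magnetic nanoparticle population properties
#'
#' Physical description of one monodisperse Fe3O4@Au particle population as
#' used by the linear-response heating chain. Defaults are the simulation
#' table values for 15 nm gold-coated magnetite: the magnetic core carries the
#' magnetite properties, the gold shell only adds hydrodynamic volume.
#'
#' The magnetic volume fraction `phi` of the suspension defaults to the tabled
#' 0.071. An alternative, documented preset takes `phi = M_s / M_d` (the
#' chord-magnetization reading, ~0.698 with the default magnetizations);
#' pass `phi = phi_saturation(M_s, M_d)` to use it.
#'
#' @param d Core diameter in m (> 0). Default 15e-9.
#' @param d_shell Non-magnetic (gold) layer thickness in m (>= 0).
#'   Default 5.5e-9.
#' @param M_d Domain magnetization of the core material, A/m. Default 4.10e4.
#' @param M_s Saturation magnetization of the suspension, A/m (<= `M_d`).
#'   Default 2.86e4.
#' @param K Magnetic anisotropy constant, J/m^3. Default 2.0e4.
#' @param eta Dynamic viscosity of the carrier fluid, Pa s. Default 2.35e-3.
#' @param rho Density of the core material, kg/m^3. Default 5196.
#' @param phi Magnetic volume fraction of the suspension, in (0, 1\].
#'   Default 0.071.
#' @param C_p Heat capacity of the core material, J/kg/K. Default 670.
#' @param tau_0 Attempt time of the Neel process, s. Default 1e-9.
#' @return A list of class `mnp_properties`.
#' @examples
#' mnp_properties()
#' mnp_properties(phi = phi_saturation())
#' @export
mnp_properties <- function(d = 15e-9, d_shell = 5.5e-9,
                           M_d = 4.10e4, M_s = 2.86e4,
                           K = 2.0e4, eta = 2.35e-3, rho = 5196,
                           phi = 0.071, C_p = 670, tau_0 = 1e-9) {
  check_number(d, "d", min = 0, strict_min = TRUE)
  check_number(d_shell, "d_shell", min = 0)
  check_number(M_d, "M_d", min = 0, strict_min = TRUE)
  check_number(M_s, "M_s", min = 0, strict_min = TRUE)
  if (M_s > M_d) abort("`M_s` must not exceed `M_d`.")
  check_number(K, "K", min = 0, strict_min = TRUE)
  check_number(eta, "eta", min = 0, strict_min = TRUE)
  check_number(rho, "rho", min = 0, strict_min = TRUE)
  check_number(phi, "phi", min = 0, max = 1, strict_min = TRUE)
  check_number(C_p, "C_p", min = 0, strict_min = TRUE)
  check_number(tau_0, "tau_0", min = 0, strict_min = TRUE)
  structure(
    list(d = d, d_shell = d_shell, M_d = M_d, M_s = M_s, K = K, eta = eta,
         rho = rho, phi = phi, C_p = C_p, tau_0 = tau_0),
    class = "mnp_properties"
  )
}

#' Saturation-based volume fraction preset
#'
#' The chord reading of the suspension volume fraction, `M_s / M_d`. With the
#' default magnetizations this is ~0.698, the only reading under which the
#' linear-response chain approaches the 214 kW/m^3 headline power.
#'
#' @param M_s,M_d Saturation and domain magnetization, A/m.
#' @return Dimensionless volume fraction.
#' @export
phi_saturation <- function(M_s = 2.86e4, M_d = 4.10e4) {
  check_number(M_s, "M_s", min = 0, strict_min = TRUE)
  check_number(M_d, "M_d", min = 0, strict_min = TRUE)
  M_s / M_d
}

#' Alternating-field excitation
#'
#' Amplitude and frequency of the applied AC magnetic field, the heating
#' duration, and the reference absolute temperature at which the
#' linear-response quantities are evaluated. The chain treats the resulting
#' power as a constant source: it is not re-evaluated against the evolving
#' tissue temperature.
#'
#' @param H_0 Field amplitude, A/m (>= 0). Default 1500 (tabled value; the
#'   simulated coil-center amplitude 750 A/m is an equally valid explicit
#'   configuration).
#' @param f Frequency, Hz (> 0). Default 571e3.
#' @param duration Heating time, s (> 0). Default 3600.
#' @param T_ref Reference absolute temperature, K (> 0). Default body
#'   temperature 310.15.
#' @return A list of class `field_excitation`.
#' @examples
#' field_excitation()
#' @export
field_excitation <- function(H_0 = 1500, f = 571e3, duration = 3600,
                             T_ref = 310.15) {
  check_number(H_0, "H_0", min = 0)
  check_number(f, "f", min = 0, strict_min = TRUE)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(T_ref, "T_ref", min = 0, strict_min = TRUE)
  structure(list(H_0 = H_0, f = f, duration = duration, T_ref = T_ref),
            class = "field_excitation")
}

# Gamma above which exp(Gamma) would overflow double precision; the particle
# is then Neel-blocked and relaxation is purely Brownian.
.neel_block_gamma <- 700

#' Magnetic core volume
#'
#' `(pi/6) d^3` for the spherical magnetic core.
#'
#' @param props An [mnp_properties()].
#' @return Volume in m^3.
#' @export
magnetic_volume <- function(props = mnp_properties()) {
  stopifnot(inherits(props, "mnp_properties"))
  pi / 6 * props$d^3
}

#' Hydrodynamic particle volume
#'
#' `(pi/6) (d + 2 d_shell)^3`: the whole particle including the non-magnetic
#' coating, which sets the Brownian rotation drag.
#'
#' @inheritParams magnetic_volume
#' @return Volume in m^3.
#' @export
hydrodynamic_volume <- function(props = mnp_properties()) {
  stopifnot(inherits(props, "mnp_properties"))
  pi / 6 * (props$d + 2 * props$d_shell)^3
}

#' Langevin parameter
#'
#' Ratio of the magnetic moment-field energy to thermal energy:
#' `xi = mu0 M_d V_m H_0 / (k_B T_ref)`.
#'
#' @inheritParams magnetic_volume
#' @param field A [field_excitation()].
#' @return Dimensionless xi >= 0.
#' @export
langevin_parameter <- function(props = mnp_properties(),
                               field = field_excitation()) {
  stopifnot(inherits(field, "field_excitation"))
  .const$mu0 * props$M_d * magnetic_volume(props) * field$H_0 /
    (.const$k_B * field$T_ref)
}

# Langevin chord slope L(xi)/(xi/3) = (3/xi)(coth xi - 1/xi), evaluated by
# series below the switchover to avoid catastrophic cancellation. At 1e-2
# the series truncation (~xi^6/4725) and the direct branch's cancellation
# error are both ~1e-12, so the two evaluations agree there to better than
# 1e-10.
langevin_slope <- function(xi, switchover = 1e-2) {
  stopifnot(all(xi >= 0))
  out <- numeric(length(xi))
  small <- xi < switchover
  out[small] <- 1 - xi[small]^2 / 15 + 2 * xi[small]^4 / 315
  xl <- xi[!small]
  out[!small] <- (3 / xl) * (1 / tanh(xl) - 1 / xl)
  out
}

#' Initial (low-field) magnetic susceptibility
#'
#' `chi_i = mu0 phi M_d^2 V_m / (3 k_B T_ref)`.
#'
#' @inheritParams langevin_parameter
#' @return Dimensionless chi_i.
#' @export
initial_susceptibility <- function(props = mnp_properties(),
                                   field = field_excitation()) {
  stopifnot(inherits(field, "field_excitation"))
  .const$mu0 * props$phi * props$M_d^2 * magnetic_volume(props) /
    (3 * .const$k_B * field$T_ref)
}

#' Equilibrium (chord) magnetic susceptibility
#'
#' The static equilibrium susceptibility follows the Langevin chord:
#' `chi_0 = chi_i (3/xi)(coth xi - 1/xi)`, which tends to `chi_i` as
#' `xi -> 0` (evaluated by series below `xi = 1e-4`).
#'
#' @inheritParams langevin_parameter
#' @return Dimensionless chi_0 in (0, chi_i\].
#' @export
equilibrium_susceptibility <- function(props = mnp_properties(),
                                       field = field_excitation()) {
  xi <- langevin_parameter(props, field)
  initial_susceptibility(props, field) * langevin_slope(xi)
}

#' Neel relaxation time
#'
#' `tau_N = (sqrt(pi)/2) tau_0 exp(Gamma)/sqrt(Gamma)` with the anisotropy
#' barrier ratio `Gamma = K V_m / (k_B T_ref)`. For `Gamma > 700` the
#' exponential overflows double precision and the particle is for all
#' purposes Neel-blocked: `Inf` is returned (with a `neel_blocked` attribute)
#' rather than a floating overflow, and downstream relaxation is purely
#' Brownian.
#'
#' @inheritParams langevin_parameter
#' @return Time in s; `Inf` when Neel-blocked.
#' @export
neel_time <- function(props = mnp_properties(), field = field_excitation()) {
  g <- anisotropy_ratio(props, field)
  if (g > .neel_block_gamma) {
    return(structure(Inf, neel_blocked = TRUE))
  }
  structure(sqrt(pi) / 2 * props$tau_0 * exp(g) / sqrt(g),
            neel_blocked = FALSE)
}

#' Anisotropy-to-thermal energy ratio
#'
#' `Gamma = K V_m / (k_B T_ref)`, the barrier height governing Neel
#' relaxation.
#'
#' @inheritParams langevin_parameter
#' @return Dimensionless Gamma > 0.
#' @export
anisotropy_ratio <- function(props = mnp_properties(),
                             field = field_excitation()) {
  stopifnot(inherits(field, "field_excitation"))
  props$K * magnetic_volume(props) / (.const$k_B * field$T_ref)
}

#' Brownian relaxation time
#'
#' `tau_B = 3 eta V_h / (k_B T_ref)`: physical rotation of the whole particle
#' against viscous drag.
#'
#' @inheritParams langevin_parameter
#' @return Time in s.
#' @export
brownian_time <- function(props = mnp_properties(),
                          field = field_excitation()) {
  stopifnot(inherits(field, "field_excitation"))
  3 * props$eta * hydrodynamic_volume(props) / (.const$k_B * field$T_ref)
}

#' Effective relaxation time
#'
#' Harmonic combination `1/tau_eff = 1/tau_N + 1/tau_B`; if the Neel channel
#' is blocked (`tau_N = Inf`) this reduces to `tau_B`.
#'
#' @param tau_N,tau_B Relaxation times in s (> 0; `tau_N` may be `Inf`).
#' @return Time in s, never exceeding `min(tau_N, tau_B)`.
#' @export
effective_time <- function(tau_N, tau_B) {
  check_number(tau_B, "tau_B", min = 0, strict_min = TRUE)
  if (is.infinite(tau_N)) return(tau_B)
  check_number(tau_N, "tau_N", min = 0, strict_min = TRUE)
  1 / (1 / tau_N + 1 / tau_B)
}

#' Volumetric heating power of the suspension (linear response theory)
#'
#' Rosensweig's small-field dissipation:
#' \deqn{Q_{nano} = \pi \mu_0 \chi_0 H_0^2 f\,
#'   \frac{2\pi f \tau_{eff}}{1 + (2\pi f \tau_{eff})^2}}
#' The Debye factor attains its maximum 1/2 exactly at
#' `2 pi f tau_eff = 1`. All intermediate quantities of the chain are
#' returned alongside the power so they can be inspected and checked
#' independently.
#'
#' @inheritParams langevin_parameter
#' @return A one-row tibble (class `heating_derived`) with columns `V_m`,
#'   `V_h` (m^3), `xi`, `chi_i`, `chi_0`, `Gamma` (dimensionless), `tau_N`,
#'   `tau_B`, `tau_eff` (s), `neel_blocked` (logical), `freq_factor`
#'   (dimensionless Debye factor) and `Q_nano` (W/m^3).
#' @examples
#' heating_power()
#' heating_power(mnp_properties(phi = phi_saturation()))
#' @export
heating_power <- function(props = mnp_properties(),
                          field = field_excitation()) {
  stopifnot(inherits(props, "mnp_properties"),
            inherits(field, "field_excitation"))
  V_m <- magnetic_volume(props)
  V_h <- hydrodynamic_volume(props)
  xi <- langevin_parameter(props, field)
  chi_i <- initial_susceptibility(props, field)
  chi_0 <- chi_i * langevin_slope(xi)
  g <- anisotropy_ratio(props, field)
  tau_N <- neel_time(props, field)
  blocked <- isTRUE(attr(tau_N, "neel_blocked"))
  tau_B <- brownian_time(props, field)
  tau_eff <- effective_time(as.numeric(tau_N), tau_B)
  x <- 2 * pi * field$f * tau_eff
  freq_factor <- x / (1 + x^2)
  Q <- pi * .const$mu0 * chi_0 * field$H_0^2 * field$f * freq_factor
  out <- tibble::tibble(
    V_m = V_m, V_h = V_h, xi = xi, chi_i = chi_i, chi_0 = chi_0,
    Gamma = g, tau_N = as.numeric(tau_N), tau_B = tau_B, tau_eff = tau_eff,
    neel_blocked = blocked, freq_factor = freq_factor, Q_nano = Q
  )
  class(out) <- c("heating_derived", class(out))
  out
}

#' Sweep the heating chain over one excitation or particle parameter
#'
#' Re-evaluates [heating_power()] for each value of one parameter (all else
#' fixed) and stacks the derived rows; convenient for amplitude/frequency/size
#' scans.
#'
#' @inheritParams langevin_parameter
#' @param over One of `"H_0"`, `"f"` (excitation) or `"d"` (core diameter).
#' @param values Numeric vector of parameter values (units of the swept
#'   field).
#' @return A tibble: one row per value, column `value` plus all
#'   [heating_power()] columns.
#' @examples
#' heating_sweep(over = "f", values = c(1e5, 5e5, 1e6))
#' @export
heating_sweep <- function(props = mnp_properties(),
                          field = field_excitation(),
                          over = c("H_0", "f", "d"), values) {
  over <- match.arg(over)
  stopifnot(is.numeric(values), length(values) >= 1)
  rows <- purrr::map(values, function(v) {
    p <- props
    fl <- field
    if (over == "d") {
      p <- mnp_properties(d = v, d_shell = props$d_shell, M_d = props$M_d,
                          M_s = props$M_s, K = props$K, eta = props$eta,
                          rho = props$rho, phi = props$phi, C_p = props$C_p,
                          tau_0 = props$tau_0)
    } else {
      fl[[over]] <- v
      fl <- field_excitation(H_0 = fl$H_0, f = fl$f, duration = fl$duration,
                             T_ref = fl$T_ref)
    }
    heating_power(p, fl)
  })
  dplyr::bind_cols(tibble::tibble(value = values), dplyr::bind_rows(rows))
}
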