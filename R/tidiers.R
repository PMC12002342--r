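# broom-style accessors. Internally every temperature is kelvin; these
# tidiers are the Celsius I/O boundary.

#' Tidy a temperature history into a long probe table
#'
#' @param x A `temperature_history` from [simulate_bioheat()].
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `probe`, `r`, `z` (m),
#'   `temperature` (K) and `temperature_C`.
#' @method tidy temperature_history
#' @export
tidy.temperature_history <- function(x, ...) {
  np <- nrow(x$probe_points)
  nt <- length(x$times)
  tibble::tibble(
    time = rep(x$times, each = np),
    probe = rep(x$probe_points$probe, times = nt),
    r = rep(x$probe_points$r, times = nt),
    z = rep(x$probe_points$z, times = nt),
    temperature = as.numeric(x$probe_T)
  ) |>
    dplyr::mutate(temperature_C = celsius(.data$temperature))
}

#' One-row summary of a temperature history
#'
#' @param x A `temperature_history`.
#' @param ... Unused.
#' @return A tibble with `peak_T_C` (domain maximum at the final time),
#'   `peak_tumor_T_C`, `final_time`, `n_steps`, `scheme`,
#'   `max_energy_residual` and `steady_bound_C` (the perfusion-dominated
#'   upper bound).
#' @method glance temperature_history
#' @export
glance.temperature_history <- function(x, ...) {
  tibble::tibble(
    peak_T_C = peak_temperature(x),
    peak_tumor_T_C = peak_temperature(x, tissue = "tumor"),
    final_time = max(x$times),
    n_steps = x$diagnostics$n_steps,
    scheme = x$scheme,
    max_energy_residual = x$diagnostics$max_energy_residual,
    steady_bound_C = celsius(steady_state_estimate(x$model))
  )
}

#' Tidy a damage field into a per-cell table
#'
#' @param x A `damage_field` from [damage_integral()].
#' @param ... Unused.
#' @return A tibble with columns `r`, `z` (m), `tissue`, `Omega`, `theta`.
#' @method tidy damage_field
#' @export
tidy.damage_field <- function(x, ...) {
  dom <- x$domain
  tibble::tibble(
    r = rep(dom$r, times = dom$Nz),
    z = rep(dom$z, each = dom$Nr),
    tissue = dom$tissue,
    Omega = as.numeric(x$Omega),
    theta = as.numeric(x$theta)
  )
}

#' One-row summary of a damage field
#'
#' @param x A `damage_field`.
#' @param ... Unused.
#' @return A tibble with tumor/skin mean and max necrotic fractions, the
#'   integration horizon and the Arrhenius parameters used.
#' @method glance damage_field
#' @export
glance.damage_field <- function(x, ...) {
  s <- damage_summary(x)
  tumor <- s[s$tissue == "tumor", ]
  skin <- s[s$tissue == "skin", ]
  tibble::tibble(
    tumor_theta_mean = tumor$theta_mean, tumor_theta_max = tumor$theta_max,
    skin_theta_mean = skin$theta_mean,
    final_time = max(x$times),
    E_a = x$params$E_a, A_f = x$params$A_f
  )
}

#' Tidy a sweep result
#'
#' @param x A `sweep_result` from [run_sweep()].
#' @param ... Unused.
#' @return A long tibble with `parameter`, `value`, `probe`, `temperature_C`
#'   (final-time probe temperatures) plus the run's `peak_T_C`.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) {
  x |>
    dplyr::select("parameter", "value", "peak_T_C", "probes") |>
    tidyr::unnest("probes")
}
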