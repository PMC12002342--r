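#' Single-parameter sensitivity sweep specification
#'
#' One full transient simulation per value of one parameter, all else held
#' at the base scenario. Recognized parameters: tissue perfusion `omega_b`
#' and metabolic heat `Q_met` (applied to both tissue domains), blood
#' density `rho_b` and heat capacity `C_b` (global), and the tumor source
#' `Q_nano`. `sweep_default_values()` returns the study's value grid for a
#' parameter.
#'
#' @param parameter One of `"omega_b"`, `"rho_b"`, `"C_b"`, `"Q_met"`,
#'   `"Q_nano"`.
#' @param values Ordered numeric vector of parameter values (SI units);
#'   defaults to [sweep_default_values()] for the parameter.
#' @param model Base [tissue_model()].
#' @param grid A [sim_grid()] used for every run.
#' @return A list of class `sweep_spec`.
#' @examples
#' sweep_spec("omega_b")
#' @export
sweep_spec <- function(parameter = c("omega_b", "rho_b", "C_b", "Q_met",
                                     "Q_nano"),
                       values = sweep_default_values(parameter),
                       model = tissue_model(), grid = sim_grid()) {
  parameter <- match.arg(parameter)
  stopifnot(is.numeric(values), inherits(model, "tissue_model"),
            inherits(grid, "sim_grid"))
  if (length(values) < 2L) {
    abort("A sweep needs at least 2 values.")
  }
  if (is.unsorted(values, strictly = TRUE) &&
      is.unsorted(rev(values), strictly = TRUE)) {
    abort("`values` must be strictly ordered.")
  }
  structure(list(parameter = parameter, values = values, model = model,
                 grid = grid),
            class = "sweep_spec")
}

#' @rdname sweep_spec
#' @export
sweep_default_values <- function(parameter = c("omega_b", "rho_b", "C_b",
                                               "Q_met", "Q_nano")) {
  parameter <- match.arg(parameter)
  switch(parameter,
    omega_b = seq(0.001, 0.005, by = 0.001),          # 1/s
    rho_b = seq(700, 1100, by = 100),                 # kg/m^3
    C_b = seq(2800, 4400, by = 400),                  # J/kg/K
    Q_met = seq(1000, 5000, by = 1000),               # W/m^3
    Q_nano = seq(110e3, 190e3, by = 20e3)             # W/m^3
  )
}

#' Run a sensitivity sweep
#'
#' Simulates the full transient problem once per value. Runs are
#' independent (no shared mutable state), so results do not depend on
#' execution order; a failing run is reported in its row and the sweep
#' continues.
#'
#' @param spec A [sweep_spec()].
#' @param scheme Time scheme passed to [simulate_bioheat()].
#' @return A tibble of class `sweep_result`, one row per value:
#'   `parameter`, `value`, `peak_T_C` (domain-maximum temperature at the
#'   final time, degrees C), list-columns `probes` (probe temperatures at
#'   the final time) and `profile` (final mid-height radial profile), and
#'   `error` (NA or the failure message).
#' @examples
#' \donttest{
#' res <- run_sweep(sweep_spec("Q_nano",
#'                             grid = sim_grid(dr = 1e-3, dz = 1e-3,
#'                                             dt = 10, duration = 600)))
#' monotonicity_report(res)
#' }
#' @export
run_sweep <- function(spec, scheme = "backward-euler") {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- purrr::map(spec$values, function(v) {
    res <- tryCatch({
      model_v <- apply_parameters(spec$model, setNames(list(v),
                                                       spec$parameter))
      hist <- simulate_bioheat(model_v, spec$grid, scheme = scheme)
      probes_final <- extract_probes(hist) |>
        dplyr::filter(.data$time == max(.data$time)) |>
        dplyr::mutate(temperature_C = celsius(.data$temperature))
      list(peak = peak_temperature(hist), probes = probes_final,
           profile = radial_profile(hist), error = NA_character_)
    }, error = function(e) {
      list(peak = NA_real_, probes = NULL, profile = NULL,
           error = conditionMessage(e))
    })
    tibble::tibble(
      parameter = spec$parameter, value = v, peak_T_C = res$peak,
      probes = list(res$probes), profile = list(res$profile),
      error = res$error
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Monotonicity verdict for sweep results
#'
#' Classifies the direction of the peak-temperature response from the signs
#' of successive differences: strictly decreasing is `"inverse"`, strictly
#' increasing `"direct"`, anything else `"non-monotone"` (ties are flagged
#' in the note). The study's qualitative result is inverse for `omega_b`,
#' `rho_b`, `C_b` and direct for `Q_met`, `Q_nano`.
#'
#' @param table A `sweep_result` from [run_sweep()] (or any data frame with
#'   `parameter`, `value`, `peak_T_C`).
#' @return A tibble with columns `parameter`, `verdict`, `note`.
#' @export
monotonicity_report <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("parameter", "value", "peak_T_C") %in% names(table)))
  table |>
    dplyr::group_by(.data$parameter) |>
    dplyr::arrange(.data$value, .by_group = TRUE) |>
    dplyr::summarise(
      verdict = {
        d <- diff(.data$peak_T_C)
        if (anyNA(d)) "non-monotone"
        else if (all(d < 0)) "inverse"
        else if (all(d > 0)) "direct"
        else "non-monotone"
      },
      note = {
        d <- diff(.data$peak_T_C)
        if (anyNA(d)) "failed run(s) present"
        else if (any(d == 0)) "zero difference between adjacent values"
        else sprintf("peak range %.3f to %.3f C",
                     min(.data$peak_T_C), max(.data$peak_T_C))
      },
      .groups = "drop"
    )
}
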