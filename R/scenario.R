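#' Reference treatment scenario
#'
#' Assembles the complete base configuration of the in-silico treatment:
#' nested tumor/skin cylinders (5 / 15 mm radii, 30 mm height) with the
#' tabled material, blood and boundary parameters, uniform tumor source
#' 214 kW/m^3, initial and arterial temperature 37 C, one hour of heating
#' on the default 0.5 mm / 1 s grid.
#'
#' @return A list of class `scenario` with elements `model`
#'   ([tissue_model()]) and `grid` ([sim_grid()]).
#' @examples
#' sc <- default_scenario()
#' sc$model$tumor_radius
#' @export
default_scenario <- function() {
  structure(list(model = tissue_model(), grid = sim_grid()),
            class = "scenario")
}

#' Write or read a scenario as JSON
#'
#' Scenarios serialize losslessly to plain JSON so every simulation input
#' can be archived next to its outputs. Reading validates through the
#' constructors, so a hand-edited file with inconsistent values is rejected.
#'
#' @param scenario A `scenario` (list with `model` and `grid`).
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns the reconstructed `scenario`.
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_scenario(default_scenario(), p)
#' sc <- read_scenario(p)
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  payload <- list(
    model = list(
      tumor_radius = scenario$model$tumor_radius,
      skin_radius = scenario$model$skin_radius,
      height = scenario$model$height,
      tumor = unclass(scenario$model$tumor),
      skin = unclass(scenario$model$skin),
      blood = unclass(scenario$model$blood),
      Q_nano = scenario$model$Q_nano, h = scenario$model$h,
      T_ext = scenario$model$T_ext, T_0 = scenario$model$T_0,
      convective_faces = as.list(scenario$model$convective_faces)
    ),
    grid = unclass(scenario$grid)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- p$model
  model <- tissue_model(
    tumor_radius = m$tumor_radius, skin_radius = m$skin_radius,
    height = m$height,
    tumor = do.call(tissue_material, m$tumor),
    skin = do.call(tissue_material, m$skin),
    blood = do.call(blood_properties, m$blood),
    Q_nano = m$Q_nano, h = m$h, T_ext = m$T_ext, T_0 = m$T_0,
    convective_faces = unlist(m$convective_faces)
  )
  grid <- do.call(sim_grid, as.list(p$grid))
  structure(list(model = model, grid = grid), class = "scenario")
}

#' Default perturbation ranges for scenario ensembles
#'
#' The single-parameter ranges of the sensitivity study: perfusion
#' 0.001-0.005 1/s, blood density 700-1100 kg/m^3, blood heat capacity
#' 2800-4400 J/kg/K, metabolic heat 1-5 kW/m^3, nanoparticle power
#' 110-190 kW/m^3.
#'
#' @return A named list of length-2 numeric ranges.
#' @export
default_ensemble_ranges <- function() {
  list(
    omega_b = c(0.001, 0.005),
    rho_b = c(700, 1100),
    C_b = c(2800, 4400),
    Q_met = c(1000, 5000),
    Q_nano = c(110e3, 190e3)
  )
}

#' Ensemble sampling specification
#'
#' @param seed Integer seed; the same seed always yields the identical
#'   ensemble (a single private random stream, no global state touched).
#' @param n Ensemble size (>= 1).
#' @param ranges Named list of `c(lower, upper)` bounds per parameter
#'   (subset of `omega_b`, `rho_b`, `C_b`, `Q_met`, `Q_nano`). Defaults to
#'   [default_ensemble_ranges()]. Degenerate ranges (lower = upper) pin the
#'   parameter.
#' @return A list of class `ensemble_spec`.
#' @examples
#' ensemble_spec(seed = 1, n = 10)
#' @export
ensemble_spec <- function(seed = 1L, n = 10L,
                          ranges = default_ensemble_ranges()) {
  check_number(seed, "seed")
  check_number(n, "n", min = 1)
  stopifnot(is.list(ranges), length(ranges) >= 1, !is.null(names(ranges)))
  bad <- setdiff(names(ranges),
                 c("omega_b", "rho_b", "C_b", "Q_met", "Q_nano"))
  if (length(bad)) {
    abort(paste0("Unknown ensemble parameter(s): ",
                 paste(bad, collapse = ", ")))
  }
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || !is.numeric(rg) || rg[1] > rg[2]) {
      abort(sprintf("Range for `%s` must be numeric c(lower, upper) with lower <= upper.", nm))
    }
  }
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 ranges = ranges),
            class = "ensemble_spec")
}

#' Sample a scenario ensemble
#'
#' Draws `n` scenarios with the listed parameters uniform within their
#' ranges (all other inputs at the base scenario), using a private seeded
#' stream. Perfusion and metabolic perturbations are applied to both tissue
#' domains; blood properties are global by construction; `Q_nano` applies to
#' the tumor source.
#'
#' @param spec An [ensemble_spec()].
#' @return A tibble with one row per draw: `id`, the sampled parameter
#'   columns, and a `model` list-column of [tissue_model()] objects.
#' @examples
#' sample_ensemble(ensemble_spec(seed = 7, n = 3))
#' @export
sample_ensemble <- function(spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  draws <- withr::with_seed(spec$seed, {
    purrr::map(spec$ranges, ~ stats::runif(spec$n, .x[1], .x[2]))
  })
  out <- tibble::as_tibble(draws)
  out <- dplyr::bind_cols(tibble::tibble(id = seq_len(spec$n)), out)
  out$model <- purrr::pmap(draws, function(...) {
    vals <- list(...)
    apply_parameters(tissue_model(), vals)
  })
  out
}

# Apply named parameter overrides to a tissue model; shared by ensembles
# and sweeps.
apply_parameters <- function(model, vals) {
  set_mat <- function(mat, field, v) {
    args <- unclass(mat)
    args[[field]] <- v
    do.call(tissue_material, args)
  }
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (nm == "omega_b") {
      model$tumor <- set_mat(model$tumor, "omega_b", v)
      model$skin <- set_mat(model$skin, "omega_b", v)
    } else if (nm == "Q_met") {
      model$tumor <- set_mat(model$tumor, "Q_met", v)
      model$skin <- set_mat(model$skin, "Q_met", v)
    } else if (nm == "rho_b") {
      model$blood <- blood_properties(v, model$blood$C_b, model$blood$T_b)
    } else if (nm == "C_b") {
      model$blood <- blood_properties(model$blood$rho_b, v, model$blood$T_b)
    } else if (nm == "Q_nano") {
      model$Q_nano <- v
    } else {
      abort(paste0("Unknown parameter `", nm, "`."))
    }
  }
  model
}

#' Synthetic single-point temperature histories
#'
#' Deterministic (seeded) time series used to exercise the damage stage
#' without a PDE solve: constant, linear ramp, ramp-then-plateau, or a
#' plateau with Gaussian noise. The constant kind enables the closed-form
#' Arrhenius oracle `Omega = A_f t exp(-E_a/(R T))`.
#'
#' @param kind One of `"constant"`, `"linear-ramp"`, `"ramp-plateau"`,
#'   `"noisy-plateau"`.
#' @param T_start,T_end Start and end/plateau temperatures, K; must lie in
#'   \[273.15, 373.15\]. Defaults 310.15 and 316.15.
#' @param ramp_time Ramp duration, s (ramp kinds). Default 300.
#' @param noise_sd Noise amplitude, K (>= 0, noisy kind). Default 0.5.
#' @param seed Seed for the noisy kind. Default 1.
#' @param dt Sampling step, s. Default 1.
#' @param duration Total duration, s. Default 3600.
#' @return A tibble with columns `time` (s) and `temperature` (K), suitable
#'   for [damage_integral()].
#' @examples
#' synthetic_history("ramp-plateau", ramp_time = 120, duration = 600)
#' @export
synthetic_history <- function(kind = c("constant", "linear-ramp",
                                       "ramp-plateau", "noisy-plateau"),
                              T_start = 310.15, T_end = 316.15,
                              ramp_time = 300, noise_sd = 0.5, seed = 1L,
                              dt = 1, duration = 3600) {
  kind <- match.arg(kind)
  check_number(T_start, "T_start", min = 273.15, max = 373.15)
  check_number(T_end, "T_end", min = 273.15, max = 373.15)
  check_number(ramp_time, "ramp_time", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  time <- seq(0, duration, by = dt)
  temperature <- switch(kind,
    "constant" = rep(T_start, length(time)),
    "linear-ramp" = T_start + (T_end - T_start) * time / duration,
    "ramp-plateau" = ,
    "noisy-plateau" = {
      if (ramp_time == 0) {
        rep(T_end, length(time))
      } else {
        ifelse(time < ramp_time,
               T_start + (T_end - T_start) * time / ramp_time, T_end)
      }
    }
  )
  if (kind == "noisy-plateau" && noise_sd > 0) {
    temperature <- temperature + withr::with_seed(
      seed, stats::rnorm(length(time), sd = noise_sd)
    )
  }
  tibble::tibble(time = time, temperature = temperature)
}
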