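# ggplot2 displays for the main result types.

#' Plot probe temperature traces
#'
#' Temperature versus time at every recorded probe, in degrees Celsius.
#'
#' @param object A `temperature_history`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot temperature_history
#' @export
autoplot.temperature_history <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 60,
                                   y = .data$temperature_C,
                                   colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Temperature (°C)",
                  colour = "Probe") +
    ggplot2::theme_minimal()
}

#' Plot a radial damage profile
#'
#' Necrotic fraction along the mid-height radius, tumor-skin interface
#' marked.
#'
#' @param object A `damage_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot damage_field
#' @export
autoplot.damage_field <- function(object, ...) {
  df <- damage_radial_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r * 1e3, y = .data$theta)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$domain$model$tumor_radius * 1e3,
                        linetype = "dashed") +
    ggplot2::labs(x = "Radius (mm)", y = "Necrotic fraction θ") +
    ggplot2::theme_minimal()
}

#' Plot sweep peak-temperature response
#'
#' Final-time peak temperature against the swept parameter value.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$peak_T_C)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$parameter),
                  y = "Peak temperature (°C)") +
    ggplot2::theme_minimal()
}

#' Temperature field heat map
#'
#' Filled (r, z) map of the stored field nearest a requested time.
#'
#' @param history A `temperature_history`.
#' @param time Time in s; default the final stored field.
#' @return A ggplot.
#' @export
plot_temperature_field <- function(history, time = NULL) {
  stopifnot(inherits(history, "temperature_history"))
  time <- time %||% max(history$field_times)
  k <- which.min(abs(history$field_times - time))
  dom <- history$domain
  df <- tibble::tibble(
    r = rep(dom$r, times = dom$Nz) * 1e3,
    z = rep(dom$z, each = dom$Nr) * 1e3,
    temperature_C = celsius(as.numeric(history$fields[[k]]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$z,
                                   fill = .data$temperature_C)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (mm)", y = "z (mm)",
                  fill = "T (°C)",
                  title = sprintf("t = %.0f s", history$field_times[k])) +
    ggplot2::theme_minimal()
}
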