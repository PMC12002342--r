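# Shared physical constants. The Boltzmann constant is kept at the rounded
# value conventional in the hyperthermia literature so that derived LRT
# quantities match hand calculations done with the same tables.
.const <- list(
  mu0   = 4e-7 * pi,      # vacuum permeability, H/m
  k_B   = 1.38e-23,       # Boltzmann constant, J/K
  R_gas = 8.3144598       # universal gas constant, J/mol/K
)

#' Physical constants used throughout the package
#'
#' Returns the vacuum permeability, Boltzmann constant and universal gas
#' constant exactly as used internally, so independent hand checks can be
#' made with identical inputs.
#'
#' @return A one-row tibble with columns `mu0` (H/m), `k_B` (J/K) and
#'   `R_gas` (J/mol/K).
#' @examples
#' physical_constants()
#' @export
physical_constants <- function() {
  tibble::tibble(mu0 = .const$mu0, k_B = .const$k_B, R_gas = .const$R_gas)
}

# Internal numeric validators --------------------------------------------

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %g (got %g).", name, min, x))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, min, x))
  }
  if (x > max) {
    abort(sprintf("`%s` must be <= %g (got %g).", name, max, x))
  }
  invisible(x)
}

#' Temperature scale conversion
#'
#' All internal computation is in kelvin; these helpers convert at the I/O
#' boundary.
#'
#' @param T_kelvin,T_celsius Temperatures in K / degrees C.
#' @return Numeric of the same shape in the other scale.
#' @examples
#' celsius(310.15)
#' kelvin(37)
#' @export
celsius <- function(T_kelvin) T_kelvin - 273.15

#' @rdname celsius
#' @export
kelvin <- function(T_celsius) T_celsius + 273.15
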