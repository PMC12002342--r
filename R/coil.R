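#' Excitation coil specification
#'
#' Geometry and drive of the multi-turn solenoid surrounding the tissue:
#' `n_turns` loops carrying `current` amperes each, wound over axial length
#' `length` at major radius `radius`. The coil is centered at z = 0; `a` and
#' `b` are the upper and lower half-lengths (`a + b = length`), symmetric by
#' default. Defaults describe the 3-turn, 15 A, 30 mm-radius, 40 mm-long
#' treatment coil.
#'
#' @param n_turns Integer number of turns (>= 1). Default 3.
#' @param current Current per loop, A. Default 15.
#' @param length Coil axial length, m (> 0). Default 0.04.
#' @param radius Coil major radius, m (> 0). Default 0.03.
#' @param a,b Upper/lower half-lengths, m; must sum to `length`.
#'   Default `length/2` each.
#' @param wire_radius Winding wire (minor) radius, m; descriptive only.
#'   Default 3e-3.
#' @return A list of class `coil_spec`.
#' @examples
#' coil_spec()
#' @export
coil_spec <- function(n_turns = 3L, current = 15, length = 0.04,
                      radius = 0.03, a = length / 2, b = length / 2,
                      wire_radius = 3e-3) {
  if (!is.numeric(n_turns) || length(n_turns) != 1L || n_turns < 1 ||
      n_turns != round(n_turns)) {
    abort("`n_turns` must be a whole number >= 1.")
  }
  check_number(current, "current")
  check_number(length, "length", min = 0, strict_min = TRUE)
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  check_number(a, "a")
  check_number(b, "b")
  if (abs(a + b - length) > 1e-12 * length) {
    abort("`a + b` must equal `length`.")
  }
  structure(list(n_turns = as.integer(n_turns), current = current,
                 length = length, radius = radius, a = a, b = b,
                 wire_radius = wire_radius),
            class = "coil_spec")
}

#' On-axis flux density of the solenoid (current-sheet solution)
#'
#' Closed-form axial flux density of a finite solenoid carrying surface
#' current `N I / l`:
#' \deqn{B_z(z) = \frac{\mu_0 N I}{2 l}\left[\frac{a - z}
#'   {\sqrt{(z-a)^2 + R^2}} + \frac{b + z}{\sqrt{(z+b)^2 + R^2}}\right]}
#' Vectorized over `z`.
#'
#' @param coil A [coil_spec()].
#' @param z Axial positions, m (coil centered at z = 0).
#' @return Flux density B_z in T, same length as `z`.
#' @examples
#' on_axis_flux_density(coil_spec(), z = 0)
#' @export
on_axis_flux_density <- function(coil = coil_spec(), z = 0) {
  stopifnot(inherits(coil, "coil_spec"), is.numeric(z))
  with(coil, .const$mu0 * n_turns * current / (2 * length) *
    ((a - z) / sqrt((z - a)^2 + radius^2) +
     (b + z) / sqrt((z + b)^2 + radius^2)))
}

# Field of a single circular loop of radius `a_loop` at axial position
# `z_loop`, carrying `current`, evaluated at cylindrical (r, z). Complete
# elliptic integral formulation; exact off axis.
single_loop_field <- function(a_loop, current, r, z, z_loop = 0) {
  zz <- z - z_loop
  alpha2 <- a_loop^2 + r^2 + zz^2 - 2 * a_loop * r
  beta2 <- a_loop^2 + r^2 + zz^2 + 2 * a_loop * r
  if (any(alpha2 <= 0)) {
    abort("Field evaluation point lies on a winding (singular).")
  }
  m <- 1 - alpha2 / beta2        # elliptic parameter k^2
  ek <- pracma::ellipke(m)
  K <- ek$k
  E <- ek$e
  beta <- sqrt(beta2)
  c0 <- .const$mu0 * current / (2 * pi)
  B_z <- c0 / beta * (K + (a_loop^2 - r^2 - zz^2) / alpha2 * E)
  B_r <- ifelse(
    r == 0, 0,
    c0 * zz / (r * beta) * (-K + (a_loop^2 + r^2 + zz^2) / alpha2 * E)
  )
  list(B_r = B_r, B_z = B_z)
}

#' Off-axis coil field by loop superposition
#'
#' Numeric field of the coil modeled as `n_loops` discrete circular loops
#' equally spaced along the winding length at
#' `z_k = -l/2 + (k + 1/2) l / n_loops`, preserving total ampere-turns
#' (`n_turns * current` split over the loops) and symmetry. Each loop field
#' uses the exact complete-elliptic-integral solution, so the result is valid
#' off axis and serves as the independent oracle for the on-axis
#' current-sheet formula.
#'
#' @param coil A [coil_spec()].
#' @param r Radial positions, m (>= 0).
#' @param z Axial positions, m. Recycled against `r`.
#' @param n_loops Number of discrete loops. Default `coil$n_turns` (the
#'   physical winding); larger values approach the continuous sheet.
#' @return A tibble with columns `r`, `z`, `B_r`, `B_z`, `B_norm` (T) and
#'   `H_norm` (A/m).
#' @examples
#' loop_superposition_field(coil_spec(), r = 0, z = 0)
#' @export
loop_superposition_field <- function(coil = coil_spec(), r = 0, z = 0,
                                     n_loops = coil$n_turns) {
  stopifnot(inherits(coil, "coil_spec"), is.numeric(r), is.numeric(z))
  if (any(r < 0)) abort("`r` must be >= 0.")
  n <- max(length(r), length(z))
  r <- rep_len(r, n)
  z <- rep_len(z, n)
  z_loops <- -coil$length / 2 +
    (seq_len(n_loops) - 0.5) * coil$length / n_loops
  I_loop <- coil$n_turns * coil$current / n_loops
  B_r <- numeric(n)
  B_z <- numeric(n)
  for (zl in z_loops) {
    fl <- single_loop_field(coil$radius, I_loop, r, z, z_loop = zl)
    B_r <- B_r + fl$B_r
    B_z <- B_z + fl$B_z
  }
  B_norm <- sqrt(B_r^2 + B_z^2)
  tibble::tibble(r = r, z = z, B_r = B_r, B_z = B_z,
                 B_norm = B_norm, H_norm = field_strength(B_norm))
}

#' Field strength from flux density in nonmagnetic media
#'
#' `H = B / mu0` (relative permeability 1, valid in tissue and air).
#'
#' @param B Flux density in T.
#' @return Field strength in A/m.
#' @examples
#' field_strength(0.7e-3) # ~557 A/m
#' @export
field_strength <- function(B) {
  stopifnot(is.numeric(B))
  B / .const$mu0
}

#' Axial field profile of the coil
#'
#' Tidy comparison table of the current-sheet closed form and the
#' loop-superposition oracle along the coil axis.
#'
#' @param coil A [coil_spec()].
#' @param z Axial positions, m.
#' @param n_loops Loops for the superposition column. Default the physical
#'   turns.
#' @return A tibble with columns `z`, `B_sheet`, `B_loops` (T), `H_sheet`,
#'   `H_loops` (A/m).
#' @examples
#' coil_axis_profile(coil_spec(), z = seq(-0.05, 0.05, by = 0.01))
#' @export
coil_axis_profile <- function(coil = coil_spec(),
                              z = seq(-0.1, 0.1, length.out = 201),
                              n_loops = coil$n_turns) {
  B_sheet <- on_axis_flux_density(coil, z)
  B_loops <- loop_superposition_field(coil, r = 0, z = z,
                                      n_loops = n_loops)$B_z
  tibble::tibble(z = z, B_sheet = B_sheet, B_loops = B_loops,
                 H_sheet = field_strength(B_sheet),
                 H_loops = field_strength(B_loops))
}
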