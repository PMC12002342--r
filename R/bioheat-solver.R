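# Axisymmetric finite-volume discretization of the Pennes bioheat equation
#
#   rho C_p dT/dt = (1/r) d/dr (r k dT/dr) + d/dz (k dT/dz)
#                   + Q_nano + Q_met + rho_b C_b omega_b (T_b - T)
#
# on cell-centered (r, z) cells. Conductivity is harmonic-averaged across
# cell faces so flux is continuous at the tumor-skin interface; the r = 0
# axis is a natural symmetry boundary (no inner face); outer faces carry
# either an insulation or a Robin (convective) condition. Time stepping is
# theta-implicit (backward Euler or Crank-Nicolson) with a constant
# coefficient matrix factorized once per run.

#' Discretize the tissue model on an axisymmetric grid
#'
#' Lays out cell-centered finite-volume cells over
#' `[0, skin_radius] x [0, height]`, labels every cell tumor or skin by its
#' radial coordinate (cell center inside `tumor_radius` -> tumor), and
#' attaches per-cell material coefficients. Cell volumes are the exact
#' annular volumes `2 pi r dr dz`, so tissue volumes are conserved to within
#' one cell layer at the interface.
#'
#' @param model A [tissue_model()].
#' @param grid A [sim_grid()]. `skin_radius` and `height` must be whole
#'   multiples of `dr` and `dz`.
#' @return A list of class `bioheat_domain` with cell coordinates, tissue
#'   labels and per-cell coefficient vectors.
#' @examples
#' dom <- build_domain(tissue_model(), sim_grid(dr = 1e-3, dz = 1e-3))
#' table(dom$tissue)
#' @export
build_domain <- function(model = tissue_model(), grid = sim_grid()) {
  stopifnot(inherits(model, "tissue_model"), inherits(grid, "sim_grid"))
  Nr <- model$skin_radius / grid$dr
  Nz <- model$height / grid$dz
  if (abs(Nr - round(Nr)) > 1e-8 || abs(Nz - round(Nz)) > 1e-8) {
    abort("`skin_radius`/`dr` and `height`/`dz` must be whole numbers.")
  }
  Nr <- as.integer(round(Nr))
  Nz <- as.integer(round(Nz))
  n_tumor_cells <- sum((seq_len(Nr) - 0.5) * grid$dr <= model$tumor_radius)
  if (n_tumor_cells < 4L) {
    abort(sprintf(
      "Grid too coarse: only %d radial cell(s) span the tumor radius (need >= 4); reduce `dr`.",
      n_tumor_cells
    ))
  }
  r <- (seq_len(Nr) - 0.5) * grid$dr
  z <- (seq_len(Nz) - 0.5) * grid$dz
  tissue_r <- ifelse(r <= model$tumor_radius, "tumor", "skin")
  tissue <- rep(tissue_r, times = Nz)
  pick <- function(field) {
    ifelse(tissue == "tumor", model$tumor[[field]], model$skin[[field]])
  }
  V <- rep(2 * pi * r * grid$dr * grid$dz, times = Nz)
  structure(list(
    Nr = Nr, Nz = Nz, dr = grid$dr, dz = grid$dz, r = r, z = z,
    tissue = tissue, V = V,
    rho = pick("rho"), C_p = pick("C_p"), k = pick("k"),
    omega_b = pick("omega_b"), Q_met = pick("Q_met"),
    Q_nano = ifelse(tissue == "tumor", model$Q_nano, 0),
    model = model, grid = grid
  ), class = "bioheat_domain")
}

#' Pennes perfusion source term
#'
#' Volumetric heat exchange with arterial blood,
#' `rho_b C_b omega_b (T_b - T)`: positive (heating) when the tissue is
#' cooler than blood, negative (the dominant cooling term) when hotter.
#'
#' @param T_tissue Tissue temperature(s), K.
#' @param material A [tissue_material()] supplying `omega_b`.
#' @param blood A [blood_properties()].
#' @return Source in W/m^3, same shape as `T_tissue`.
#' @examples
#' perfusion_source(311.15, tumor_material(), blood_properties())
#' @export
perfusion_source <- function(T_tissue, material, blood = blood_properties()) {
  stopifnot(inherits(material, "tissue_material"),
            inherits(blood, "blood_properties"), is.numeric(T_tissue))
  blood$rho_b * blood$C_b * material$omega_b * (blood$T_b - T_tissue)
}

# Assemble the constant operators for one domain. Returns mass, stiffness,
# perfusion and Robin diagonals plus the constant source vector.
assemble_operators <- function(domain) {
  Nr <- domain$Nr; Nz <- domain$Nz
  dr <- domain$dr; dz <- domain$dz
  N <- Nr * Nz
  model <- domain$model
  idx <- function(i, j) i + (j - 1L) * Nr

  # radial faces between (i, j) and (i + 1, j); face radius i * dr
  i <- rep(seq_len(Nr - 1L), times = Nz)
  j <- rep(seq_len(Nz), each = Nr - 1L)
  p <- idx(i, j); q <- idx(i + 1L, j)
  kf <- 2 * domain$k[p] * domain$k[q] / (domain$k[p] + domain$k[q])
  Gr <- 2 * pi * (i * dr) * dz * kf / dr

  # axial faces between (i, j) and (i, j + 1); face area 2 pi r dr
  i2 <- rep(seq_len(Nr), times = Nz - 1L)
  j2 <- rep(seq_len(Nz - 1L), each = Nr)
  p2 <- idx(i2, j2); q2 <- idx(i2, j2 + 1L)
  kf2 <- 2 * domain$k[p2] * domain$k[q2] / (domain$k[p2] + domain$k[q2])
  Gz <- 2 * pi * domain$r[i2] * dr * kf2 / dz

  A <- Matrix::sparseMatrix(
    i = c(p, q, p, q, p2, q2, p2, q2),
    j = c(q, p, p, q, q2, p2, p2, q2),
    x = c(-Gr, -Gr, Gr, Gr, -Gz, -Gz, Gz, Gz),
    dims = c(N, N)
  )

  # Robin (convective) faces
  rb <- numeric(N)
  if ("lateral" %in% model$convective_faces) {
    cells <- idx(Nr, seq_len(Nz))
    rb[cells] <- rb[cells] + model$h * 2 * pi * model$skin_radius * dz
  }
  if ("bottom" %in% model$convective_faces) {
    cells <- idx(seq_len(Nr), 1L)
    rb[cells] <- rb[cells] + model$h * 2 * pi * domain$r * dr
  }
  if ("top" %in% model$convective_faces) {
    cells <- idx(seq_len(Nr), Nz)
    rb[cells] <- rb[cells] + model$h * 2 * pi * domain$r * dr
  }

  blood <- model$blood
  Pd <- domain$V * blood$rho_b * blood$C_b * domain$omega_b
  Md <- domain$V * domain$rho * domain$C_p
  S0 <- domain$V * (domain$Q_nano + domain$Q_met) + Pd * blood$T_b +
    rb * model$T_ext

  list(A = A, Md = Md, Pd = Pd, rb = rb, S0 = S0)
}

# Bilinear interpolation weights of points onto cell centers, with constant
# extrapolation beyond the outermost centers (second-order correct at the
# symmetry axis where dT/dr = 0).
interp_weights <- function(domain, points) {
  Nr <- domain$Nr; Nz <- domain$Nz
  N <- Nr * Nz
  np <- nrow(points)
  rows <- integer(0); cols <- integer(0); w <- numeric(0)
  for (p in seq_len(np)) {
    rp <- min(max(points$r[p], domain$r[1]), domain$r[Nr])
    zp <- min(max(points$z[p], domain$z[1]), domain$z[Nz])
    i0 <- min(max(findInterval(rp, domain$r), 1L), Nr - 1L)
    j0 <- min(max(findInterval(zp, domain$z), 1L), Nz - 1L)
    tr <- (rp - domain$r[i0]) / domain$dr
    tz <- (zp - domain$z[j0]) / domain$dz
    cij <- c(i0 + (j0 - 1L) * Nr, i0 + 1L + (j0 - 1L) * Nr,
             i0 + j0 * Nr, i0 + 1L + j0 * Nr)
    wij <- c((1 - tr) * (1 - tz), tr * (1 - tz), (1 - tr) * tz, tr * tz)
    rows <- c(rows, rep(p, 4L)); cols <- c(cols, cij); w <- c(w, wij)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(np, N))
}

#' Default probe locations
#'
#' Six named probes P1..P6 equally spaced along the mid-height radial line
#' from the axis to the outer skin surface.
#'
#' @param model A [tissue_model()].
#' @return A tibble with columns `probe`, `r`, `z` (m).
#' @export
default_probes <- function(model = tissue_model()) {
  tibble::tibble(
    probe = paste0("P", 1:6),
    r = seq(0, model$skin_radius, length.out = 6),
    z = model$height / 2
  )
}

#' Initialize a bioheat solver state
#'
#' Assembles the finite-volume operators, factorizes the implicit system
#' once, and returns a stepping state at `T_0`. Used by
#' [simulate_bioheat()]; exposed so single steps can be examined directly
#' with [bioheat_step()].
#'
#' @param model A [tissue_model()].
#' @param grid A [sim_grid()].
#' @param scheme `"backward-euler"` (default, theta = 1) or
#'   `"crank-nicolson"` (theta = 1/2). Both are unconditionally stable;
#'   Crank-Nicolson is second-order in time.
#' @return A list of class `bioheat_state` with the current temperature
#'   vector `T` (K), elapsed `time` (s) and the assembled operators.
#' @export
bioheat_init <- function(model = tissue_model(), grid = sim_grid(),
                         scheme = c("backward-euler", "crank-nicolson")) {
  scheme <- match.arg(scheme)
  theta <- if (scheme == "backward-euler") 1 else 0.5
  domain <- build_domain(model, grid)
  ops <- assemble_operators(domain)
  N <- domain$Nr * domain$Nz
  Rmat <- ops$A + Matrix::Diagonal(N, ops$Pd + ops$rb)
  LHS <- Matrix::Diagonal(N, ops$Md / grid$dt) + theta * Rmat
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(LHS))
  structure(list(
    domain = domain, ops = ops, Rmat = Rmat, chol = chol, theta = theta,
    scheme = scheme, dt = grid$dt, T = rep(model$T_0, N), time = 0,
    max_residual = 0
  ), class = "bioheat_state")
}

#' Advance the bioheat state by implicit time steps
#'
#' Performs `n_steps` theta-implicit steps of the assembled axisymmetric
#' operator, solving the factorized linear system each step. A discrete
#' energy-balance residual (stored heat minus net sources, relative to the
#' source magnitude) is accumulated in `state$max_residual`; a residual
#' above `1e-8` raises a hard error with diagnostics, since it indicates a
#' linear-solver failure.
#'
#' @param state A `bioheat_state` from [bioheat_init()].
#' @param n_steps Number of steps to take. Default 1.
#' @return The advanced `bioheat_state`.
#' @export
bioheat_step <- function(state, n_steps = 1L) {
  stopifnot(inherits(state, "bioheat_state"))
  ops <- state$ops
  Minv_dt <- ops$Md / state$dt
  s_scale <- max(abs(ops$S0), Minv_dt * max(abs(state$T)) * 1e-6)
  for (s in seq_len(n_steps)) {
    To <- state$T
    rhs <- Minv_dt * To - (1 - state$theta) * as.numeric(state$Rmat %*% To) +
      ops$S0
    Tn <- as.numeric(Matrix::solve(state$chol, rhs, system = "A"))
    res <- Minv_dt * (Tn - To) +
      state$theta * as.numeric(state$Rmat %*% Tn) +
      (1 - state$theta) * as.numeric(state$Rmat %*% To) - ops$S0
    rel <- max(abs(res)) / s_scale
    state$max_residual <- max(state$max_residual, rel)
    if (!is.finite(rel) || rel > 1e-8) {
      abort(sprintf(
        "Linear solve failed at t = %g s: energy residual %.3e (scheme %s, dt %g).",
        state$time + state$dt, rel, state$scheme, state$dt
      ))
    }
    state$T <- Tn
    state$time <- state$time + state$dt
  }
  state
}

#' Simulate the transient bioheat problem
#'
#' Runs the implicit axisymmetric Pennes solve from `T_0` for the configured
#' duration, recording every probe at every step and the full temperature
#' field every `field_interval` seconds (plus the initial and final states).
#'
#' @inheritParams bioheat_init
#' @param probes A tibble of named probe locations (columns `probe`, `r`,
#'   `z`); defaults to [default_probes()]. Probes must lie inside the
#'   domain.
#' @return An object of class `temperature_history`: stored fields (K) on
#'   the cell-centered grid, per-step probe temperatures, the domain, and
#'   solver diagnostics. Use [tidy()] / [glance()] / [autoplot()] or
#'   [extract_probes()] to work with it.
#' @examples
#' \donttest{
#' hist <- simulate_bioheat(tissue_model(),
#'                          sim_grid(dr = 1e-3, dz = 1e-3, dt = 10,
#'                                   duration = 600))
#' glance(hist)
#' }
#' @export
simulate_bioheat <- function(model = tissue_model(), grid = sim_grid(),
                             scheme = c("backward-euler", "crank-nicolson"),
                             probes = NULL) {
  scheme <- match.arg(scheme)
  probes <- probes %||% default_probes(model)
  stopifnot(is.data.frame(probes),
            all(c("probe", "r", "z") %in% names(probes)))
  if (any(probes$r < 0 | probes$r > model$skin_radius |
          probes$z < 0 | probes$z > model$height)) {
    abort("All probe points must lie inside the domain.")
  }
  state <- bioheat_init(model, grid, scheme)
  domain <- state$domain
  W <- interp_weights(domain, probes)
  n_steps <- round(grid$duration / grid$dt)
  if (abs(n_steps * grid$dt - grid$duration) > 1e-9 * grid$duration) {
    abort("`duration` must be a whole number of time steps `dt`.")
  }
  times <- seq(0, by = grid$dt, length.out = n_steps + 1)
  probe_T <- matrix(NA_real_, nrow = nrow(probes), ncol = n_steps + 1)
  probe_T[, 1] <- as.numeric(W %*% state$T)
  rec_every <- max(1L, round(grid$field_interval / grid$dt))
  field_steps <- unique(c(0L, seq(rec_every, n_steps, by = rec_every),
                          n_steps))
  fields <- vector("list", length(field_steps))
  names(fields) <- as.character(times[field_steps + 1L])
  fields[[1]] <- matrix(state$T, nrow = domain$Nr)
  fi <- 2L
  for (s in seq_len(n_steps)) {
    state <- bioheat_step(state, 1L)
    probe_T[, s + 1] <- as.numeric(W %*% state$T)
    if (fi <= length(field_steps) && s == field_steps[fi]) {
      fields[[fi]] <- matrix(state$T, nrow = domain$Nr)
      fi <- fi + 1L
    }
  }
  structure(list(
    model = model, grid = grid, domain = domain, scheme = scheme,
    times = times, probe_points = tibble::as_tibble(probes),
    probe_T = probe_T,
    field_times = times[field_steps + 1L], fields = fields,
    diagnostics = list(n_steps = n_steps,
                       max_energy_residual = state$max_residual)
  ), class = "temperature_history")
}

#' Perfusion-dominated steady-state temperature bound
#'
#' Conduction-free local balance of the bioheat equation in the tumor:
#' `T_b + (Q_nano + Q_met) / (rho_b C_b omega_b)`. Conduction only removes
#' heat from the hottest point, so the simulated peak can never exceed this
#' estimate (maximum-principle sanity bound used in the tests).
#'
#' @param model A [tissue_model()].
#' @return Temperature in K.
#' @examples
#' steady_state_estimate(tissue_model()) - 310.15 # ~4.46 K rise
#' @export
steady_state_estimate <- function(model = tissue_model()) {
  stopifnot(inherits(model, "tissue_model"))
  if (model$tumor$omega_b <= 0) {
    abort("Steady-state estimate requires tumor perfusion `omega_b` > 0.")
  }
  model$blood$T_b + (model$Q_nano + model$tumor$Q_met) /
    (model$blood$rho_b * model$blood$C_b * model$tumor$omega_b)
}

#' Interpolate stored fields at arbitrary points
#'
#' Bilinear interpolation of every stored temperature field at the given
#' points. A point at an exact cell center returns the nodal value.
#'
#' @param history A `temperature_history` from [simulate_bioheat()].
#' @param points A tibble with columns `probe`, `r`, `z` (m); points must
#'   lie inside the domain.
#' @return A tibble with columns `time` (s), `probe`, `temperature` (K).
#' @export
extract_probes <- function(history, points = default_probes(history$model)) {
  stopifnot(inherits(history, "temperature_history"), is.data.frame(points),
            all(c("probe", "r", "z") %in% names(points)))
  model <- history$model
  if (any(points$r < 0 | points$r > model$skin_radius |
          points$z < 0 | points$z > model$height)) {
    abort("All probe points must lie inside the domain.")
  }
  W <- interp_weights(history$domain, points)
  vals <- vapply(history$fields,
                 function(f) as.numeric(W %*% as.numeric(f)),
                 numeric(nrow(points)))
  vals <- matrix(vals, nrow = nrow(points))
  tibble::tibble(
    time = rep(history$field_times, each = nrow(points)),
    probe = rep(points$probe, times = length(history$field_times)),
    temperature = as.numeric(vals)
  )
}

#' Peak temperature of a simulation
#'
#' Domain-maximum temperature of the stored field nearest the requested
#' time (default: the final stored field), optionally restricted to one
#' tissue.
#'
#' @param history A `temperature_history`.
#' @param time Time in s; default the end of the run.
#' @param tissue `"any"` (default), `"tumor"` or `"skin"`.
#' @return Temperature in degrees Celsius.
#' @export
peak_temperature <- function(history, time = NULL,
                             tissue = c("any", "tumor", "skin")) {
  stopifnot(inherits(history, "temperature_history"))
  tissue <- match.arg(tissue)
  time <- time %||% max(history$field_times)
  k <- which.min(abs(history$field_times - time))
  Tf <- as.numeric(history$fields[[k]])
  if (tissue != "any") Tf <- Tf[history$domain$tissue == tissue]
  celsius(max(Tf))
}

#' Mid-height radial temperature profile
#'
#' Temperatures along the radial cell centers at mid-height, for the stored
#' field nearest each requested time.
#'
#' @param history A `temperature_history`.
#' @param times Times in s; default the final stored time.
#' @return A tibble with columns `time` (s), `r` (m), `tissue`,
#'   `temperature` (K) and `temperature_C`.
#' @export
radial_profile <- function(history, times = NULL) {
  stopifnot(inherits(history, "temperature_history"))
  times <- times %||% max(history$field_times)
  dom <- history$domain
  j_mid <- max(1L, round(dom$Nz / 2))
  purrr::map_dfr(times, function(tt) {
    k <- which.min(abs(history$field_times - tt))
    Tf <- history$fields[[k]][, j_mid]
    tibble::tibble(
      time = history$field_times[k], r = dom$r,
      tissue = dom$tissue[seq_len(dom$Nr)],
      temperature = Tf, temperature_C = celsius(Tf)
    )
  })
}

#' @export
print.temperature_history <- function(x, ...) {
  cat("<temperature_history>\n")
  cat(sprintf("  grid: %d x %d cells (dr %.2g mm, dz %.2g mm), dt %g s, %s\n",
              x$domain$Nr, x$domain$Nz, x$domain$dr * 1e3, x$domain$dz * 1e3,
              x$grid$dt, x$scheme))
  cat(sprintf("  duration: %g s; %d stored fields; %d probes\n",
              max(x$times), length(x$fields), nrow(x$probe_points)))
  cat(sprintf("  peak temperature at end: %.2f C\n", peak_temperature(x)))
  invisible(x)
}
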