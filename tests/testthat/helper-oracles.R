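# Independent scalar oracle for the linear-response heating chain: a
# straight transliteration of the physics, deliberately not calling any
# package internals, so the packaged chain is checked against a second
# implementation.
lrt_oracle <- function(D, d_shell, M_d, K, eta, phi, tau_0, H_0, f, Temp) {
  mu0 <- 4e-7 * pi
  kB <- 1.38e-23
  Vm <- pi / 6 * D^3
  Vh <- pi / 6 * (D + 2 * d_shell)^3
  xi <- mu0 * M_d * Vm * H_0 / (kB * Temp)
  chi_i <- mu0 * phi * M_d^2 * Vm / (3 * kB * Temp)
  chi_0 <- chi_i * (3 / xi) * (1 / tanh(xi) - 1 / xi)
  G <- K * Vm / (kB * Temp)
  tau_N <- sqrt(pi) / 2 * tau_0 * exp(G) / sqrt(G)
  tau_B <- 3 * eta * Vh / (kB * Temp)
  tau <- 1 / (1 / tau_N + 1 / tau_B)
  x <- 2 * pi * f * tau
  pi * mu0 * chi_0 * H_0^2 * f * x / (1 + x^2)
}

# Random LRT parameter sets (valid, un-blocked) for the dual-route check.
# The field amplitude is chosen to place the Langevin parameter in
# [0.1, 5]: there the naive direct chord evaluation in the oracle is
# well-conditioned (cancellation error < 1e-12), so a 1e-10 comparison is
# meaningful, and the nonlinear part of the chord is exercised.
random_lrt_params <- function(n, seed = 42L) {
  mu0 <- 4e-7 * pi
  kB <- 1.38e-23
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      p <- list(
        D = runif(1, 8e-9, 20e-9),
        d_shell = runif(1, 0, 10e-9),
        M_d = runif(1, 2e4, 8e4),
        K = runif(1, 5e3, 4e4),
        eta = runif(1, 1e-3, 5e-3),
        phi = runif(1, 0.01, 0.7),
        tau_0 = runif(1, 1e-10, 5e-9),
        f = runif(1, 1e5, 1e6),
        Temp = runif(1, 300, 320)
      )
      xi_target <- runif(1, 0.1, 5)
      p$H_0 <- xi_target * kB * p$Temp /
        (mu0 * p$M_d * (pi / 6 * p$D^3))
      p
    })
  })
}

# Coarse but fully resolved test grid: 1 mm cells (5 tumor cells), large
# steps. Fast enough to run many transient solves inside the suite.
coarse_grid <- function(dt = 5, duration = 3600, field_interval = 60) {
  sim_grid(dr = 1e-3, dz = 1e-3, dt = dt, duration = duration,
           field_interval = field_interval)
}

# One shared coarse transient solve of the reference scenario, computed on
# first use and reused across test files.
base_history <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_bioheat(tissue_model(), coarse_grid())
    }
    cache
  }
})
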