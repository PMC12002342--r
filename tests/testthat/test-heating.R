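test_that("particle volumes follow the sphere formulas", {
  p <- mnp_properties(d = 15e-9, d_shell = 5.5e-9)
  expect_equal(magnetic_volume(p), pi / 6 * (15e-9)^3)
  expect_equal(magnetic_volume(p), 1.767e-24, tolerance = 1e-3)
  expect_equal(hydrodynamic_volume(p), pi / 6 * (26e-9)^3)
  expect_equal(hydrodynamic_volume(p), 9.20e-24, tolerance = 1e-3)
  # degenerate shell: hydrodynamic = magnetic
  p0 <- mnp_properties(d_shell = 0)
  expect_equal(hydrodynamic_volume(p0), magnetic_volume(p0))
  # strictly increasing in shell thickness
  vh <- vapply(seq(0, 10e-9, length.out = 6),
               function(s) hydrodynamic_volume(mnp_properties(d_shell = s)),
               numeric(1))
  expect_true(all(diff(vh) > 0))
})

test_that("Langevin parameter is linear in field amplitude", {
  p <- mnp_properties()
  f0 <- field_excitation(H_0 = 0)
  expect_equal(langevin_parameter(p, f0), 0)
  xi <- langevin_parameter(p, field_excitation(H_0 = 1500))
  # direct scalar evaluation oracle
  expect_equal(xi, 4e-7 * pi * 4.10e4 * (pi / 6 * (15e-9)^3) * 1500 /
                 (1.38e-23 * 310.15))
  expect_equal(xi, 0.0319, tolerance = 1e-3)
  expect_equal(langevin_parameter(p, field_excitation(H_0 = 3000)), 2 * xi)
})

test_that("equilibrium susceptibility follows the Langevin chord", {
  p <- mnp_properties()
  # vanishing-field limit: chi_0 -> chi_i
  f_small <- field_excitation(H_0 = 1e-6)
  expect_equal(equilibrium_susceptibility(p, f_small),
               initial_susceptibility(p, f_small), tolerance = 1e-12)
  # xi = 3 chord value (direct evaluation oracle): scale H_0 to land there
  f1 <- field_excitation(H_0 = 1500)
  H3 <- 1500 * 3 / langevin_parameter(p, f1)
  f3 <- field_excitation(H_0 = H3)
  expect_equal(equilibrium_susceptibility(p, f3) /
                 initial_susceptibility(p, f3),
               (3 / 3) * (1 / tanh(3) - 1 / 3), tolerance = 1e-12)
  # chord factor monotone decreasing and bounded in (0, 1]
  xi <- 10^seq(-3, 2, length.out = 40)
  slope <- magnetherm:::langevin_slope(xi)
  expect_true(all(diff(slope) < 0))
  expect_true(all(slope > 0 & slope <= 1))
  # series and direct branches agree at the switchover
  sw <- 1e-2
  expect_equal(magnetherm:::langevin_slope(sw, switchover = sw * 2),
               magnetherm:::langevin_slope(sw, switchover = sw / 2),
               tolerance = 1e-10)
})

test_that("relaxation times match the direct oracles", {
  p <- mnp_properties()
  fl <- field_excitation()
  G <- 2.0e4 * (pi / 6 * (15e-9)^3) / (1.38e-23 * 310.15)
  expect_equal(anisotropy_ratio(p, fl), G)
  expect_equal(G, 8.26, tolerance = 1e-3)
  expect_equal(as.numeric(neel_time(p, fl)),
               sqrt(pi) / 2 * 1e-9 * exp(G) / sqrt(G))
  # Gamma = 1 closed form via a scaled anisotropy constant
  p1 <- mnp_properties(K = 2.0e4 / G)
  expect_equal(as.numeric(neel_time(p1, fl)),
               sqrt(pi) / 2 * 1e-9 * exp(1), tolerance = 1e-10)
  # monotone increasing in K
  tn <- vapply(seq(1e4, 4e4, length.out = 5),
               function(k) as.numeric(neel_time(mnp_properties(K = k), fl)),
               numeric(1))
  expect_true(all(diff(tn) > 0))

  tb <- brownian_time(p, fl)
  expect_equal(tb, 3 * 2.35e-3 * (pi / 6 * (26e-9)^3) / (1.38e-23 * 310.15))
  expect_equal(tb, 1.52e-5, tolerance = 1e-2)
  # linear in viscosity and hydrodynamic volume
  expect_equal(brownian_time(mnp_properties(eta = 4.70e-3), fl), 2 * tb)
  expect_equal(brownian_time(mnp_properties(d = 15e-9 * 2^(1 / 3),
                                            d_shell = 5.5e-9 * 2^(1 / 3)),
                             fl),
               2 * tb, tolerance = 1e-12)
})

test_that("Neel blocking is flagged instead of overflowing", {
  # a 70 nm core at the default anisotropy is far beyond the barrier limit
  p <- mnp_properties(d = 70e-9)
  fl <- field_excitation()
  tn <- neel_time(p, fl)
  expect_true(is.infinite(tn))
  expect_true(attr(tn, "neel_blocked"))
  expect_equal(effective_time(as.numeric(tn), 1e-5), 1e-5)
  h <- heating_power(p, fl)
  expect_true(h$neel_blocked)
  expect_equal(h$tau_eff, h$tau_B)
  expect_true(is.finite(h$Q_nano))
})

test_that("effective time is the harmonic combination and a lower bound", {
  expect_equal(effective_time(2, 2), 1)
  expect_equal(effective_time(1.19e-6, 1.52e-5),
               1 / (1 / 1.19e-6 + 1 / 1.52e-5))
  withr::with_seed(5, {
    for (i in 1:50) {
      a <- 10^runif(1, -9, -3)
      b <- 10^runif(1, -9, -3)
      expect_lte(effective_time(a, b), min(a, b))
    }
  })
})

test_that("heating chain matches the independent scalar oracle", {
  # tabled inputs
  h <- heating_power(mnp_properties(), field_excitation())
  expect_equal(h$Q_nano,
               lrt_oracle(15e-9, 5.5e-9, 4.10e4, 2.0e4, 2.35e-3, 0.071,
                          1e-9, 1500, 571e3, 310.15),
               tolerance = 1e-12)
  expect_equal(h$Q_nano, 2.5e4, tolerance = 0.02)
  # 100 random parameter sets, dual-route agreement to 1e-10
  for (pp in random_lrt_params(100)) {
    got <- heating_power(
      mnp_properties(d = pp$D, d_shell = pp$d_shell, M_d = pp$M_d,
                     M_s = 0.7 * pp$M_d, K = pp$K, eta = pp$eta,
                     phi = pp$phi, tau_0 = pp$tau_0),
      field_excitation(H_0 = pp$H_0, f = pp$f, T_ref = pp$Temp)
    )$Q_nano
    want <- lrt_oracle(pp$D, pp$d_shell, pp$M_d, pp$K, pp$eta, pp$phi,
                       pp$tau_0, pp$H_0, pp$f, pp$Temp)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("power vanishes without field and is deterministic", {
  h0 <- heating_power(field = field_excitation(H_0 = 0))
  expect_equal(h0$Q_nano, 0)
  a <- heating_power(mnp_properties(), field_excitation())
  b <- heating_power(mnp_properties(), field_excitation())
  expect_identical(a, b)
})

test_that("power scales as H_0^2 in the linear regime", {
  sw <- heating_sweep(over = "H_0", values = 100 * 2^(0:5))
  expect_true(all(sw$xi < 0.1))
  ratio <- sw$Q_nano / sw$value^2
  expect_lt(max(ratio) / min(ratio) - 1, 0.01)
})

test_that("frequency response follows the Debye dissipation factor", {
  # with a frequency-independent relaxation time, Q ~ x^2/(1 + x^2) with
  # x = 2 pi f tau: it vanishes at low frequency, rises monotonically and
  # saturates at pi mu0 chi_0 H_0^2 / (2 pi tau) in the high-frequency limit
  f_grid <- 10^seq(2, 10, length.out = 81)
  sw <- heating_sweep(over = "f", values = f_grid)
  expect_lt(sw$Q_nano[1], 1e-3 * max(sw$Q_nano))
  expect_true(all(diff(sw$Q_nano) > 0))
  base <- heating_power()
  asymptote <- pi * physical_constants()$mu0 * base$chi_0 * 1500^2 /
    (2 * pi * base$tau_eff)
  expect_equal(sw$Q_nano[nrow(sw)], asymptote, tolerance = 1e-3)
  # the Debye factor itself is unimodal in f, peaking at exactly 1/2 when
  # 2 pi f tau_eff = 1
  sgn <- sign(diff(sw$freq_factor))
  expect_equal(sum(diff(sgn) != 0), 1)
  at_peak <- heating_power(
    field = field_excitation(f = 1 / (2 * pi * base$tau_eff))
  )
  expect_equal(at_peak$freq_factor, 0.5, tolerance = 1e-12)
})

test_that("saturation-fraction preset lands near the headline power", {
  h <- heating_power(mnp_properties(phi = phi_saturation()))
  expect_lt(abs(log(h$Q_nano / 2.14e5)), log(1.5))
})

test_that("particle and field validation rejects unphysical inputs", {
  expect_error(mnp_properties(M_s = 5e4, M_d = 4e4), "M_s")
  expect_error(mnp_properties(phi = 0), "phi")
  expect_error(mnp_properties(phi = 1.2), "phi")
  expect_error(field_excitation(f = 0), "f")
  expect_error(field_excitation(H_0 = -1), "H_0")
})
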