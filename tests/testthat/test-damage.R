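test_that("constant-temperature damage equals the closed form", {
  par <- arrhenius_params()
  for (dt in c(60, 10, 1)) {
    hist <- synthetic_history("constant", T_start = 316.15, dt = dt,
                              duration = 3600)
    dmg <- damage_integral(hist, par)
    closed <- par$A_f * 3600 * exp(-par$E_a / (par$R_gas * 316.15))
    # trapezoid of a constant rate is exact at any dt
    expect_equal(dmg$Omega[nrow(dmg)], closed, tolerance = 1e-12)
  }
  # one hour at 43 C accrues only ~3 % damage with these kinetics
  closed <- 3.1e98 * 3600 * exp(-6.27e5 / (8.3144598 * 316.15))
  expect_equal(closed, 0.03, tolerance = 0.1)
})

test_that("the tabled 6.27e8 J/mol activation energy freezes all damage", {
  hist <- synthetic_history("constant", T_start = 319.15, dt = 60,
                            duration = 3600)
  dmg <- damage_integral(hist, arrhenius_params(E_a = 6.27e8))
  expect_equal(max(dmg$Omega), 0)
  expect_equal(max(dmg$theta), 0)
})

test_that("necrotic fraction maps the damage index correctly", {
  expect_equal(necrotic_fraction(0), 0)
  expect_equal(necrotic_fraction(log(2)), 0.5)
  expect_equal(necrotic_fraction(4.6), 0.99, tolerance = 1e-3)
  expect_error(necrotic_fraction(-0.1), "non-negative")
  om <- seq(0, 30, length.out = 100)
  th <- necrotic_fraction(om)
  expect_true(all(th >= 0 & th < 1))
  expect_true(all(diff(th) > 0))
})

test_that("damage trajectories are monotone and window-additive", {
  hist <- synthetic_history("ramp-plateau", T_start = 310.15,
                            T_end = 318.15, ramp_time = 600, dt = 5,
                            duration = 3600)
  dmg <- damage_integral(hist)
  expect_true(all(diff(dmg$Omega) >= 0))
  expect_true(all(dmg$theta >= 0 & dmg$theta < 1))
  # additivity over any split at a stored sample
  for (t1 in c(300, 600, 1800, 3595)) {
    first <- damage_integral(hist[hist$time <= t1, ])
    second <- hist[hist$time >= t1, ]
    second$time <- second$time - t1
    second <- damage_integral(second)
    total <- first$Omega[nrow(first)] + second$Omega[nrow(second)]
    expect_equal(total, dmg$Omega[nrow(dmg)], tolerance = 1e-12)
  }
})

test_that("trapezoidal damage converges under dt refinement", {
  omega_at <- function(dt) {
    hist <- synthetic_history("linear-ramp", T_start = 310.15,
                              T_end = 319.15, dt = dt, duration = 3600)
    d <- damage_integral(hist)
    d$Omega[nrow(d)]
  }
  vals <- vapply(c(16, 8, 4, 2, 1), omega_at, numeric(1))
  ref <- omega_at(0.25)
  errs <- abs(vals - ref)
  # second-order convergence: each halving shrinks the error ~4x
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5))
  expect_lt(errs[length(errs)] / ref, 1e-6)
})

test_that("degenerate and invalid histories are handled", {
  empty <- damage_integral(tibble::tibble(time = numeric(),
                                          temperature = numeric()))
  expect_identical(nrow(empty), 0L)
  one <- damage_integral(tibble::tibble(time = 0, temperature = 320))
  expect_equal(one$Omega, 0)
  expect_error(
    damage_integral(tibble::tibble(time = c(0, 0, 1),
                                   temperature = rep(320, 3))),
    "strictly increasing"
  )
})

test_that("field damage summarises per tissue and falls with radius", {
  # synthetic uniform-temperature history on a real domain: uniform theta
  dom <- build_domain(tissue_model(), coarse_grid())
  uniform <- matrix(316.15, nrow = dom$Nr, ncol = dom$Nz)
  fake <- structure(
    list(fields = list(uniform, uniform), field_times = c(0, 3600),
         domain = dom),
    class = "temperature_history"
  )
  dmg_u <- damage_integral(fake)
  s <- damage_summary(dmg_u)
  expect_equal(s$theta_min, s$theta_max, tolerance = 1e-12)
  expect_equal(s$theta_min, s$theta_mean, tolerance = 1e-12)

  # simulated scenario: hotter tumor accrues more damage than skin, and the
  # radial damage profile inherits the monotone temperature profile
  dmg <- damage_integral(base_history())
  s2 <- damage_summary(dmg)
  expect_gte(s2$theta_mean[s2$tissue == "tumor"],
             s2$theta_mean[s2$tissue == "skin"])
  prof <- damage_radial_profile(dmg)
  expect_true(all(diff(prof$theta) <= 0))
  expect_true(all(dmg$theta >= 0 & dmg$theta < 1))
})
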