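test_that("domain labeling and volumes are exact", {
  dom <- build_domain(tissue_model(), sim_grid())
  # 10 radial cells span the 5 mm tumor at dr = 0.5 mm
  expect_equal(sum(dom$tissue[seq_len(dom$Nr)] == "tumor"), 10)
  expect_equal(dom$Nr, 30L)
  expect_equal(dom$Nz, 60L)
  # cell volumes integrate the cylinders exactly
  m <- tissue_model()
  expect_equal(sum(dom$V[dom$tissue == "tumor"]),
               pi * m$tumor_radius^2 * m$height, tolerance = 1e-12)
  expect_equal(sum(dom$V), pi * m$skin_radius^2 * m$height,
               tolerance = 1e-12)
})

test_that("degenerate geometry and coarse grids are rejected", {
  expect_error(tissue_model(tumor_radius = 15e-3, skin_radius = 15e-3),
               "strictly less")
  expect_error(build_domain(tissue_model(), sim_grid(dr = 1.5e-3, dz = 1.5e-3)),
               "too coarse")
  expect_error(build_domain(tissue_model(), sim_grid(dr = 0.7e-3)),
               "whole numbers")
})

test_that("perfusion source has the Pennes sign convention and slope", {
  blood <- blood_properties()
  mat <- tumor_material()
  expect_equal(perfusion_source(blood$T_b, mat, blood), 0)
  # 1 K above arterial temperature: cooling at rho_b C_b omega_b
  expect_equal(perfusion_source(311.15, mat, blood),
               -1050 * 3617 * 1.34e-2)
  dT <- seq(-3, 3)
  expect_equal(perfusion_source(310.15 + dT, mat, blood),
               -1050 * 3617 * 1.34e-2 * dT)
})

test_that("uniform blood-temperature state is a fixed point of the step", {
  um <- tissue_material(1090, 3421, 0.563, 1.34e-2, 0)
  m <- tissue_model(tumor = um, skin = um, Q_nano = 0, h = 0,
                    T_0 = 310.15)
  st <- bioheat_init(m, coarse_grid(dt = 1, duration = 10))
  st <- bioheat_step(st, 1L)
  expect_lt(max(abs(st$T - 310.15)), 1e-12)
})

test_that("uniform perfusion-only cooling matches the ODE closed form", {
  # uniform material and initial state, insulated, no sources: every cell
  # relaxes as T_b + (T_0 - T_b) exp(-t/tau), tau = rho C_p/(rho_b C_b w_b)
  um <- tissue_material(1090, 3421, 0.563, 1.34e-2, 0)
  m <- tissue_model(tumor = um, skin = um, Q_nano = 0, h = 0,
                    T_0 = kelvin(45))
  hist <- simulate_bioheat(
    m, coarse_grid(dt = 0.5, duration = 150, field_interval = 10),
    scheme = "crank-nicolson"
  )
  tau <- 1090 * 3421 / (1050 * 3617 * 1.34e-2)
  expect_equal(tau, 73.3, tolerance = 1e-3)
  td <- tidy(hist)
  td <- td[td$probe == "P1" & td$time > 0, ]
  rel <- abs((td$temperature - 310.15) / 8 - exp(-td$time / tau)) /
    exp(-td$time / tau)
  expect_lt(max(rel), 1e-4)
  # spot value at t = tau: 37 + 8/e ~ 39.94 C
  at_tau <- 310.15 + 8 * exp(-1)
  expect_equal(celsius(at_tau), 39.94, tolerance = 1e-4)
})

test_that("halving dt leaves the 60-minute solution unchanged", {
  h1 <- simulate_bioheat(tissue_model(), coarse_grid(dt = 2))
  h2 <- simulate_bioheat(tissue_model(), coarse_grid(dt = 1))
  expect_lt(abs(peak_temperature(h1) - peak_temperature(h2)), 1e-3)
})

test_that("steady-state estimate bounds the simulated peak from above", {
  m <- tissue_model()
  est <- steady_state_estimate(m)
  expect_equal(est - 310.15,
               (2.14e5 + 13080) / (1050 * 3617 * 1.34e-2))
  expect_equal(est - 310.15, 4.46, tolerance = 1e-3)
  m0 <- tissue_model(Q_nano = 0,
                     tumor = tissue_material(1090, 3421, 0.563, 1.34e-2, 0))
  expect_equal(steady_state_estimate(m0), m0$blood$T_b)
  expect_error(
    steady_state_estimate(
      tissue_model(tumor = tissue_material(1090, 3421, 0.563, 0, 13080))
    ),
    "perfusion"
  )
  hist <- base_history()
  expect_lt(peak_temperature(hist), celsius(est))
})

test_that("zero-source solve relaxes to the arterial equilibrium", {
  m <- tissue_model(
    Q_nano = 0,
    tumor = tissue_material(1090, 3421, 0.563, 1.34e-2, 0),
    skin = tissue_material(1109, 3391, 0.37, 1.96e-3, 0),
    T_0 = kelvin(45)
  )
  hist <- simulate_bioheat(m, coarse_grid(dt = 5))
  final <- hist$fields[[length(hist$fields)]]
  expect_lt(max(abs(final - 310.15)), 0.05)
})

test_that("temperature decreases monotonically along the radius", {
  prof <- radial_profile(base_history())
  expect_true(all(diff(prof$temperature) < 0))
  # and the P1 (center) probe dominates P6 (outer) at every time
  td <- tidy(base_history())
  wide <- tidyr::pivot_wider(td[, c("time", "probe", "temperature")],
                             names_from = "probe",
                             values_from = "temperature")
  expect_true(all(wide$P1 >= wide$P6))
})

test_that("probe interpolation is exact at nodes and bilinear at midpoints", {
  hist <- base_history()
  dom <- hist$domain
  i <- 3L; j <- 4L
  node <- tibble::tibble(probe = "node", r = dom$r[i], z = dom$z[j])
  got <- extract_probes(hist, node)
  want <- vapply(hist$fields, function(f) f[i, j], numeric(1))
  expect_equal(got$temperature, unname(want), tolerance = 1e-12)
  # midpoint of a 2x2 cell-center block equals the corner mean
  mid <- tibble::tibble(probe = "mid",
                        r = (dom$r[i] + dom$r[i + 1]) / 2,
                        z = (dom$z[j] + dom$z[j + 1]) / 2)
  gotm <- extract_probes(hist, mid)
  wantm <- vapply(hist$fields, function(f) {
    mean(f[i:(i + 1), j:(j + 1)])
  }, numeric(1))
  expect_equal(gotm$temperature, unname(wantm), tolerance = 1e-12)
})

test_that("out-of-domain probes are rejected", {
  hist <- base_history()
  bad <- tibble::tibble(probe = "X", r = 0.02, z = 0.015)
  expect_error(extract_probes(hist, bad), "inside the domain")
  expect_error(
    simulate_bioheat(tissue_model(), coarse_grid(duration = 10, dt = 5),
                     probes = bad),
    "inside the domain"
  )
})

test_that("discrete energy balance closes to solver precision", {
  hist <- base_history()
  expect_lt(hist$diagnostics$max_energy_residual, 1e-6)
  g <- glance(hist)
  expect_identical(g$n_steps, 720)
  expect_equal(g$peak_T_C, peak_temperature(hist))
})

test_that("tidied history carries probes in both temperature scales", {
  td <- tidy(base_history())
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$probe), paste0("P", 1:6))
  expect_equal(td$temperature_C, td$temperature - 273.15)
  expect_equal(nrow(td), 6 * (720 + 1))
})
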