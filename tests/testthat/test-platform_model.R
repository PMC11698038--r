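test_that("load-deflection calibration recovers stiffness", {
  # hand arithmetic: 0.010 * 9.81 / 0.0289
  k <- stiffness_from_load_deflection(
    data.frame(applied_mass = 0.010, deflection = 0.0289))
  expect_equal(k, 0.010 * 9.81 / 0.0289, tolerance = 1e-12)
  expect_equal(k, 3.394, tolerance = 5e-4)

  expect_equal(
    stiffness_from_load_deflection(
      data.frame(applied_mass = 0.050, deflection = 0.001)),
    490.5
  )

  # linearity: proportional loading gives identical k
  d <- 0.003
  k1 <- stiffness_from_load_deflection(
    data.frame(applied_mass = 0.001, deflection = d))
  k2 <- stiffness_from_load_deflection(
    data.frame(applied_mass = 0.002, deflection = 2 * d))
  expect_equal(k1, k2)

  expect_error(
    stiffness_from_load_deflection(
      data.frame(applied_mass = 0.01, deflection = 0)),
    "positive"
  )
})

test_that("calibration recovers a known stiffness from generated deflections", {
  k_true <- 17.3
  masses <- c(0.001, 0.002, 0.010, 0.020, 0.050, 0.100)
  clean <- data.frame(applied_mass = masses,
                      deflection = masses * 9.81 / k_true)
  expect_equal(stiffness_from_load_deflection(clean), k_true)
  expect_equal(stiffness_from_load_deflection(clean, method = "ls"), k_true)

  # additive deflection noise at 0.2 mm reading error: the smallest
  # deflection (~0.6 mm under 1 g) dominates the error of the mean-of-k
  # combiner, so the bound is loose; the least-squares combiner, weighted
  # towards the large deflections, stays much tighter
  set.seed(11)
  errs <- replicate(50, {
    noisy <- clean
    noisy$deflection <- noisy$deflection + rnorm(6, 0, 2e-4)
    c(mean = abs(stiffness_from_load_deflection(noisy) / k_true - 1),
      ls = abs(stiffness_from_load_deflection(noisy, method = "ls") /
                 k_true - 1))
  })
  expect_lt(mean(errs["mean", ]), 0.10)
  expect_lt(mean(errs["ls", ]), 0.02)
})

test_that("cantilever tip stiffness follows Euler-Bernoulli scaling", {
  k <- cantilever_tip_stiffness(10e9, 0.025, 0.002, 0.55)
  expect_equal(k, 3 * 10e9 * (0.025 * 0.002^3 / 12) / 0.55^3)
  expect_equal(k, 3.005, tolerance = 1e-3)
  # cubic scalings
  expect_equal(cantilever_tip_stiffness(10e9, 0.025, 0.002, 0.275) / k, 8)
  expect_equal(cantilever_tip_stiffness(10e9, 0.025, 0.004, 0.55) / k, 8)
  expect_error(cantilever_tip_stiffness(10e9, 0.025, 0.002, 0), "positive")

  # monotone decreasing in free length over a fine grid
  L <- seq(0.05, 0.6, by = 0.01)
  ks <- cantilever_tip_stiffness(10e9, 0.025, 0.002, L)
  expect_true(all(diff(ks) < 0))
})

test_that("effective tip mass lumps the overhang by 33/140", {
  plat <- platform_spec(0.61, 0.025, 0.002, 6.34e-3)
  expect_equal(effective_tip_mass(plat, 0.61), 33 / 140 * 6.34e-3)
  expect_equal(effective_tip_mass(plat, 0.61), 1.494e-3, tolerance = 1e-3)
  expect_equal(effective_tip_mass(plat, 0.61, coefficient = 1), 6.34e-3)
  expect_equal(effective_tip_mass(plat, 0), 0)
  expect_error(effective_tip_mass(plat, 0.7), "within")
})

test_that("synthetic stiffness profiles satisfy the decreasing-k invariant", {
  plat <- platform_spec(0.61, 0.025, 0.002, 6.34e-3, elastic_modulus = 2.6e9)
  prof <- synthetic_stiffness_profile(plat, n_lines = 10)
  expect_equal(nrow(prof), 10)
  expect_true(all(diff(prof$k_N_per_m) < 0))
  expect_true(all(prof$k_N_per_m > 0))
  expect_equal(prof$position_m, 0.05 * (1:10))
})

test_that("profiles built from calibration tables validate and convert units", {
  # generate a bench-format CSV from known per-line stiffnesses
  k_lines <- c(400, 50, 14.8, 6.25)
  rows <- do.call(rbind, lapply(seq_along(k_lines), function(i) {
    m <- c(0.010, 0.020)
    data.frame(platform_id = "A", line_index = i, applied_mass_g = m * 1000,
               deflection_mm = m * 9.81 / k_lines[i] * 1000)
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  calib <- read_load_deflection(path)
  prof <- stiffness_profile(calib)
  expect_equal(prof$k_N_per_m, k_lines, tolerance = 1e-10)

  # a non-decreasing profile violates the platform geometry
  bad <- calib
  bad$deflection[bad$line_index == 2] <- bad$deflection[bad$line_index == 4]
  expect_error(stiffness_profile(bad), "decrease strictly")
})

test_that("stiffness and mass ratios divide jumper over platform", {
  expect_equal(stiffness_ratio(3.42, 24), 3.42 / 24)
  expect_equal(stiffness_ratio(3.42, 24), 0.1425)
  expect_equal(stiffness_ratio(3.42, 1.0), 3.42)
  expect_equal(stiffness_ratio(5, 5), 1.0)
  expect_equal(mass_ratio(1.13e-3, 1.01e-3), 1.119, tolerance = 1e-3)
  expect_equal(mass_ratio(1.13e-3, 6.34e-3), 0.178, tolerance = 2e-3)
  expect_equal(mass_ratio(2, 2), 1.0)
  expect_error(stiffness_ratio(1, 0), "positive")
  expect_error(mass_ratio(1, 0), "positive")
})
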