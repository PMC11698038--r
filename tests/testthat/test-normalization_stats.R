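make_jump_row <- function(animal_id, platform_id, line_index = NA_integer_,
                          v = 1.44, t = 0.028, elev = 43.5, k_p = NA_real_) {
  m <- 1.13e-3; mm <- muscle_mass_default(m)
  KE <- kinetic_energy(m, v)
  data.frame(
    animal_id = animal_id, platform_id = platform_id,
    line_index = line_index,
    time_to_takeoff_s = t, velocity_m_s = v, elevation_deg = elev,
    platform_displacement_m = 0, platform_angle_deg = 0,
    acceleration_distance_m = 0.026, acceleration_m_s2 = v / t,
    kinetic_energy_J = KE,
    kinetic_energy_density_J_kg = KE / mm,
    power_W = KE / t, power_density_W_kg = KE / t / mm,
    k_g_N_m = 3.4, k_p_N_m = k_p, stiffness_ratio = NA_real_,
    mass_ratio = NA_real_, stringsAsFactors = FALSE
  )
}

test_that("control means average one animal's control jumps only", {
  jt <- rbind(
    make_jump_row("a", "control", v = 1.4),
    make_jump_row("a", "control", v = 1.5),
    make_jump_row("a", "control", v = 1.3),
    make_jump_row("b", "control", v = 2.0)
  )
  cm <- control_means(jt, "a")
  expect_equal(unname(cm["velocity_m_s"]), 1.4)
  expect_equal(unname(control_means(jt, "b")["velocity_m_s"]), 2.0)
  expect_error(control_means(jt, "c"), "c")
  # single control jump is its own mean; identical jumps have zero spread
  expect_equal(unname(control_means(jt, "b")["elevation_deg"]), 43.5)
})

test_that("normalization is ratio everywhere but difference for elevation", {
  jt <- rbind(
    make_jump_row("a", "control", v = 1.44, elev = 43.5),
    make_jump_row("a", "A", 5L, v = 1.08, elev = 40.0, k_p = 2.0)
  )
  nz <- normalize_jumps(jt, k_g_split = 3.42)
  expect_equal(nrow(nz), 1)
  expect_equal(nz$rel_velocity, 0.75)
  expect_equal(nz$diff_elevation_deg, -3.5)
  expect_equal(nz$regime, "compliant")

  # jump identical to the control mean: ratios 1, difference 0
  jt2 <- rbind(
    make_jump_row("a", "control"),
    make_jump_row("a", "A", 1L, k_p = 600)
  )
  nz2 <- normalize_jumps(jt2, k_g_split = 3.42)
  expect_equal(nz2$rel_velocity, 1.0)
  expect_equal(nz2$rel_kinetic_energy_density, 1.0)
  expect_equal(nz2$rel_power_density, 1.0)
  expect_equal(nz2$diff_elevation_deg, 0)
  expect_equal(nz2$regime, "stiff")
})

test_that("normalizing controls by their own mean gives unit mean ratios", {
  set.seed(8)
  jt <- do.call(rbind, lapply(1:4, function(j)
    make_jump_row("a", "control", v = 1.44 + rnorm(1, 0, 0.1),
                  t = 0.028 + runif(1, -0.003, 0.003),
                  elev = 43.5 + rnorm(1, 0, 3))))
  # treat the controls as if they were experimental to exercise the math
  jt$platform_id <- c("control", "control", "control", "control")
  ctrl_as_exp <- jt
  ctrl_as_exp$platform_id <- "A"
  ctrl_as_exp$line_index <- 1L
  ctrl_as_exp$k_p_N_m <- 5
  nz <- normalize_jumps(rbind(jt, ctrl_as_exp), k_g_split = 3.42)
  expect_equal(mean(nz$rel_velocity), 1.0, tolerance = 1e-12)
  expect_equal(mean(nz$rel_power_density), 1.0, tolerance = 1e-12)
  expect_equal(mean(nz$diff_elevation_deg), 0, tolerance = 1e-12)
})

test_that("regime assignment is exhaustive, exclusive, and ties go stiff", {
  jt <- rbind(
    make_jump_row("a", "control"),
    make_jump_row("a", "A", 9L, k_p = 1.0),
    make_jump_row("a", "A", 5L, k_p = 3.42),
    make_jump_row("a", "A", 1L, k_p = 600)
  )
  nz <- normalize_jumps(jt, k_g_split = 3.42)
  expect_equal(nz$regime, c("compliant", "stiff", "stiff"))
  expect_true(all(nz$regime %in% c("compliant", "stiff")))
})

test_that("one-sample test matches closed-form t and handles degeneracy", {
  # symmetric sample about the null: t = 0, p = 1
  res <- one_sample_test(c(0.9, 1.0, 1.1), 1.0)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # n = 4 closed form: mean 1.275, sd 0.0645497
  vals <- c(1.2, 1.3, 1.25, 1.35)
  res2 <- one_sample_test(vals, 1.0)
  t_manual <- (mean(vals) - 1) / (sd(vals) / 2)
  expect_equal(res2$statistic, t_manual)
  expect_lt(res2$p_value, 0.05)

  expect_error(one_sample_test(c(2, 2, 2, 2), 1.0), "variance")
  expect_error(one_sample_test(1.5, 1.0), "at least two")
})

test_that("one-sample test is location-equivariant and reports a signed-rank fallback", {
  set.seed(21)
  vals <- rnorm(12, 1.1, 0.2)
  a <- one_sample_test(vals, 1.0)
  b <- one_sample_test(vals + 3.7, 4.7)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)

  # a heavily skewed sample fails the normality check
  skewed <- c(rep(1.01, 9), 4, 5, 6)
  res <- one_sample_test(skewed, 1.0)
  expect_false(res$normal)
  expect_true(is.finite(res$wilcoxon_p))
})

test_that("regime mixed models recover a known stiffness slope", {
  d <- make_slope_data(slope = 0.23, seed = 42)
  fit <- regime_model(d, "rel_velocity", "compliant")
  expect_gt(fit$slope_ci[1], 0.23 - 4 * fit$slope_se)
  expect_true(fit$slope_ci[1] <= 0.23 && 0.23 <= fit$slope_ci[2])

  # single animal cannot support the per-animal random intercept
  single <- d[d$animal_id == "a01", ]
  expect_error(regime_model(single, "rel_velocity", "compliant"),
               "two animals")
})

test_that("stiff-regime models drop a non-significant stiffness-by-platform interaction", {
  # two platform types, common slope: interaction should be pruned
  d <- make_slope_data(slope = 0.001, intercept = 1, regime = "stiff",
                       k_p = seq(5, 600, length.out = 6), seed = 9)
  dB <- make_slope_data(slope = 0.001, intercept = 1, regime = "stiff",
                        k_p = seq(100, 700, length.out = 4), seed = 10)
  dB$platform_id <- "B"
  fit <- regime_model(rbind(d, dB), "rel_velocity", "stiff")
  expect_true(fit$interaction_dropped)
  expect_true(all(c("k_p_N_m", "platform_id") %in% rownames(fit$anova)))

  # a strong genuine interaction is retained
  dC <- dB
  dC$rel_velocity <- dC$rel_velocity + 0.02 * dC$k_p_N_m
  fit2 <- regime_model(rbind(d, dC), "rel_velocity", "stiff")
  expect_false(fit2$interaction_dropped)
})

test_that("per-line tests run the battery across variables and lines", {
  set.seed(5)
  jt <- do.call(rbind, c(
    lapply(1:4, function(i) {
      do.call(rbind, lapply(1:3, function(j)
        make_jump_row(sprintf("a%d", i), "control",
                      v = rnorm(1, 1.44, 0.05), elev = rnorm(1, 43.5, 2))))
    }),
    lapply(1:4, function(i) {
      do.call(rbind, lapply(c(1L, 2L), function(ln)
        make_jump_row(sprintf("a%d", i), "A", ln,
                      v = rnorm(1, 1.1, 0.05), elev = rnorm(1, 42, 2),
                      k_p = c(600, 80)[ln])))
    })
  ))
  nz <- normalize_jumps(jt, k_g_split = 3.42)
  tests <- per_line_tests(nz)
  expect_true(all(c("rel_velocity", "diff_elevation_deg") %in%
                    tests$variable))
  expect_equal(sort(unique(tests$line_index)), c(1L, 2L))
  v_tests <- tests[tests$variable == "rel_velocity", ]
  expect_true(all(v_tests$n == 4))
  expect_true(all(v_tests$p >= 0 & v_tests$p <= 1, na.rm = TRUE))
})
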