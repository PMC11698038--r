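test_that("rigid-limit take-off speed matches the single-spring closed form", {
  # pinned platform
  cfg <- sim_config(k_p = Inf, m_p_eff = Inf, noise_sd = 0)
  res <- simulate_jump(cfg)
  v_closed <- spring_launch_speed(cfg$k_g_true, cfg$m_g, cfg$x_true)
  expect_equal(res$takeoff_speed, v_closed, tolerance = 1e-6)
  # quarter period of the half-cosine launch
  expect_equal(res$takeoff_time, (pi / 2) * sqrt(cfg$m_g / cfg$k_g_true),
               tolerance = 1e-6)

  # immovable-substrate limit: huge platform mass, finite stiffness
  cfg2 <- sim_config(k_p = 24, m_p_eff = 1e3, noise_sd = 0)
  res2 <- simulate_jump(cfg2)
  expect_equal(res2$takeoff_speed, v_closed, tolerance = 1e-3)
  expect_lt(res2$max_platform_displacement, 1e-5)

  # extremely stiff finite platform behaves rigidly too
  cfg3 <- sim_config(k_p = 3.42e6, m_p_eff = 2.5e-4, noise_sd = 0)
  expect_equal(simulate_jump(cfg3)$takeoff_speed, v_closed,
               tolerance = 1e-3)
})

test_that("energy ledger conserves total energy without damping", {
  cfg <- sim_config(k_p = 24, m_p_eff = 2.5e-4,
                    platform_damping_ratio = 0, noise_sd = 0)
  res <- simulate_jump(cfg)
  drift <- max(abs(res$ledger$total - res$initial_energy))
  expect_lt(drift / res$initial_energy, 1e-6)
  # stored-energy identity
  expect_equal(res$initial_energy, 0.5 * cfg$k_g_true * cfg$x_true^2)
  # with damping the ledger still closes (dissipation tracked) in contact
  cfg_d <- sim_config(k_p = 24, m_p_eff = 2.5e-4,
                      platform_damping_ratio = 0.05, noise_sd = 0)
  res_d <- simulate_jump(cfg_d)
  in_contact <- res_d$ledger$time <= res_d$takeoff_time
  drift_d <- max(abs(res_d$ledger$total[in_contact] - res_d$initial_energy))
  expect_lt(drift_d / res_d$initial_energy, 1e-6)
  expect_gt(utils::tail(res_d$ledger$dissipated[in_contact], 1), 0)
})

test_that("momentum bookkeeping closes against the wall impulse", {
  for (cfg in list(sim_config(k_p = 24, m_p_eff = 2.5e-4, noise_sd = 0),
                   sim_config(k_p = 2, m_p_eff = 1.2e-3, noise_sd = 0),
                   sim_config(k_p = Inf, m_p_eff = Inf, noise_sd = 0))) {
    res <- simulate_jump(cfg)
    p_scale <- cfg$m_g * res$takeoff_speed
    expect_lt(abs(res$momentum_residual) / p_scale, 1e-6)
  }
})

test_that("the stiff light platform recoils before take-off", {
  cfg <- sim_config(k_p = 24, m_p_eff = 2.5e-4, noise_sd = 0)
  res <- simulate_jump(cfg)
  expect_true(res$recoil_before_takeoff)
  expect_lt(res$max_displacement_time, res$takeoff_time)
  expect_gt(res$platform_velocity_at_takeoff, 0)
})

test_that("rendered recordings are deterministic and noise-free at sd 0", {
  cfg <- sim_config(k_p = Inf, m_p_eff = Inf, noise_sd = 0)
  res <- simulate_jump(cfg)
  rr <- render_recording(res, cfg)
  # noise-free positions equal the sampled truth along the thrust axis
  theta <- cfg$elevation_deg * pi / 180
  idx <- rr$recording$body_series$frame + 1L
  expect_equal(rr$recording$body_series$x,
               res$frames$s_g[idx] * cos(theta), tolerance = 1e-12)
  expect_equal(rr$recording$body_series$y,
               res$frames$s_g[idx] * sin(theta), tolerance = 1e-12)

  cfg_n <- sim_config(k_p = Inf, m_p_eff = Inf, noise_sd = 1e-4, seed = 77)
  a <- render_recording(simulate_jump(cfg_n), cfg_n)
  b <- render_recording(simulate_jump(cfg_n), cfg_n)
  expect_identical(a$recording$body_series$x, b$recording$body_series$x)
  expect_identical(a$recording$body_series$y, b$recording$body_series$y)
})

test_that("pipeline velocity on a noise-free rigid recording matches ballistic truth", {
  cfg <- sim_config(k_p = Inf, m_p_eff = Inf, noise_sd = 0)
  res <- simulate_jump(cfg)
  rr <- render_recording(res, cfg)
  v_est <- take_off_velocity(rr$recording)
  expect_lt(abs(v_est / res$takeoff_speed - 1), 0.015)
  # elevation estimate matches the configured launch direction
  expect_equal(elevation(rr$recording, 0), cfg$elevation_deg,
               tolerance = 0.1)
})

test_that("platform sweeps reproduce the compliance regimes", {
  base <- sim_config(noise_sd = 0)
  kg <- base$k_g_true
  sw <- sweep_platforms(base, k_p_values = kg * c(0.3, 0.6, 0.99, 5, 50),
                        m_p_values = c(1e-4, 1.2e-3))
  expect_equal(nrow(sw), 10)
  expect_true(all(sw$rel_speed > 0 & sw$rel_speed <= 1 + 1e-9))
  expect_equal(sw$rel_KE, sw$rel_speed^2, tolerance = 1e-12)
  # compliant platforms cost take-off speed
  expect_true(all(sw$rel_speed[sw$k_ratio > 1] < 0.95))
  # KE is non-decreasing in k_p below the jumper stiffness at light mass
  light <- sw[sw$m_p_eff == 1e-4 & sw$k_ratio > 1, ]
  light <- light[order(light$k_p), ]
  expect_true(all(diff(light$rel_KE) > 0))
  expect_error(sweep_platforms(base, numeric(0), 1e-4), "non-empty")
})

test_that("non-physical configurations are rejected", {
  expect_error(sim_config(m_g = 0), "positive")
  expect_error(sim_config(k_p = -1), "positive")
  expect_error(sim_config(elevation_deg = 190), "between")
  expect_error(sim_config(noise_sd = -1), ">= 0")
})
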