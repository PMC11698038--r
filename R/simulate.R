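#' Configuration of a coupled jumper-platform simulation
#'
#' The simulator reduces the launch to dynamics along the leg-thrust axis:
#' a jumper of mass `m_g` driven by a pre-loaded linear leg spring
#' (stiffness `k_g_true`, stroke `x_true`) pushing off a cantilever tip
#' lumped as a spring-mass (`k_p`, `m_p_eff`, viscous damping set by
#' `platform_damping_ratio`). Contact is unilateral: the legs push but
#' cannot pull, and take-off occurs at full leg extension, where the
#' contact force of the linear leg spring simultaneously reaches zero.
#' The take-off velocity vector is resolved at `elevation_deg` above the
#' horizontal; flight is ballistic thereafter (gravity excluded, matching
#' the energy bookkeeping of the analysis pipeline).
#'
#' Defaults instantiate the study system: a 1.13 g jumper with effective
#' stiffness 3.42 N m^-1 and the stroke implied by 15.6 mm leg segments
#' opening to 113 degrees; platforms span ~0.3x to 200x the jumper
#' stiffness. `k_p = Inf` (or `m_p_eff = Inf`) pins the platform: the
#' rigid-substrate control case.
#'
#' @param m_g jumper mass, kg.
#' @param k_g_true leg-spring stiffness, N m^-1.
#' @param x_true leg-spring stroke (acceleration distance), m.
#' @param elevation_deg take-off elevation above horizontal, degrees.
#' @param m_p_eff effective platform tip mass, kg (see
#'   [effective_tip_mass()]); `Inf` for an immovable substrate.
#' @param k_p platform tip stiffness, N m^-1; `Inf` for rigid.
#' @param platform_damping_ratio viscous damping ratio of the platform
#'   mode (dimensionless).
#' @param frame_rate camera frame rate for rendered output, frames s^-1.
#' @param noise_sd digitization noise s.d. per coordinate, m.
#' @param seed RNG seed for rendered noise.
#' @param rtol,atol integrator tolerances.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_g = 1.13e-3,
                       k_g_true = 3.42,
                       x_true = sqrt(2 * 0.0156^2 * (1 - cos(113 * pi / 180))),
                       elevation_deg = 43.5,
                       m_p_eff = 2.5e-4,
                       k_p = 24,
                       platform_damping_ratio = 0.02,
                       frame_rate = 1000,
                       noise_sd = 1e-4,
                       seed = 1L,
                       rtol = 1e-10, atol = 1e-12) {
  if (m_g <= 0 || k_g_true <= 0 || x_true <= 0)
    stop("jumper mass, stiffness and stroke must be positive")
  if (k_p <= 0 || m_p_eff <= 0)
    stop("platform stiffness and effective mass must be positive (use Inf for rigid)")
  if (elevation_deg <= 0 || elevation_deg >= 180)
    stop("take-off elevation must lie strictly between 0 and 180 degrees")
  if (platform_damping_ratio < 0) stop("damping ratio must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  structure(
    list(m_g = m_g, k_g_true = k_g_true, x_true = x_true,
         elevation_deg = elevation_deg, m_p_eff = m_p_eff, k_p = k_p,
         platform_damping_ratio = platform_damping_ratio,
         frame_rate = frame_rate, noise_sd = noise_sd,
         seed = as.integer(seed), rtol = rtol, atol = atol),
    class = "sim_config"
  )
}

is_rigid <- function(config) {
  !is.finite(config$k_p) || !is.finite(config$m_p_eff)
}

#' Simulate a spring-actuated jump from a compliant cantilever tip
#'
#' Integrates, along the thrust axis, the contact-phase equations
#' \deqn{m_g \ddot s_g = F, \qquad
#'       m_p \ddot s_p = -k_p s_p - c \dot s_p - F,}
#' with leg force \eqn{F = k_g (x_{true} - (s_g - s_p))} while the leg
#' extension is below the stroke. Take-off (leg fully extended, contact
#' force zero) is located by the integrator's root finder; flight is
#' ballistic afterwards. The returned energy ledger tracks leg-spring
#' potential energy, jumper kinetic energy, platform elastic and kinetic
#' energy, and viscous dissipation at every sampled frame; with zero
#' damping the ledger total is conserved to integrator tolerance.
#'
#' @param config a [sim_config()].
#' @param post_takeoff_s ballistic time simulated past take-off, s; must
#'   cover the 10 ms velocity window plus a margin.
#' @return A `sim_result` list: `frames` (per-frame positions `s_g`, `s_p`
#'   and velocities along the axis plus the energy ledger), `takeoff_time`,
#'   `takeoff_speed`, `takeoff_velocity` (2-D vector), `max_displacement_time`,
#'   `max_platform_displacement`, `recoil_before_takeoff`,
#'   `platform_velocity_at_takeoff`, `momentum_residual`, and the `config`.
#' @export
simulate_jump <- function(config, post_takeoff_s = 0.015) {
  stopifnot(inherits(config, "sim_config"))
  rigid <- is_rigid(config)
  m_g <- config$m_g; k_g <- config$k_g_true; x_true <- config$x_true
  k_p <- config$k_p; m_p <- config$m_p_eff
  c_p <- if (rigid) 0 else
    2 * config$platform_damping_ratio * sqrt(k_p * m_p)

  # contact phase: y = (s_g, v_g, s_p, v_p, dissipated, wall_impulse)
  deriv <- function(t, y, parms) {
    e <- y[1] - y[3]
    F <- k_g * (x_true - e)
    if (rigid) {
      # wall reaction transmitted through the pinned platform equals +F
      list(c(y[2], F / m_g, 0, 0, 0, F))
    } else {
      f_wall <- -k_p * y[3] - c_p * y[4]
      list(c(y[2], F / m_g, y[4], (f_wall - F) / m_p,
             c_p * y[4]^2, f_wall))
    }
  }
  # take-off: leg extension reaches the full stroke (contact force -> 0)
  rootfun <- function(t, y, parms) x_true - (y[1] - y[3])

  t_max <- 60 * sqrt(m_g / k_g)  # many rigid-case quarter-periods
  times <- seq(0, t_max, by = 1 / config$frame_rate)
  sol <- deSolve::lsodar(
    y = c(0, 0, 0, 0, 0, 0), times = times, func = deriv, parms = NULL,
    rootfunc = rootfun, rtol = config$rtol, atol = config$atol
  )
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("integrator failure for config: m_g=", m_g, " k_g=", k_g,
         " k_p=", k_p, " m_p=", m_p)
  if (is.null(attr(sol, "troot")))
    stop("no take-off within ", signif(t_max, 3),
         " s; non-physical config: k_p=", k_p, " m_p=", m_p)

  t_to <- attr(sol, "troot")
  final <- sol[nrow(sol), -1]
  v_to <- final[2]
  s_g_to <- final[1]
  contact <- sol[sol[, "time"] < t_to, , drop = FALSE]

  # dense frames: contact-phase samples, then ballistic continuation
  frame_times <- seq(0, t_to + post_takeoff_s, by = 1 / config$frame_rate)
  in_contact <- frame_times < t_to
  n_pre <- sum(in_contact)
  s_g <- c(contact[seq_len(n_pre), 2],
           s_g_to + v_to * (frame_times[!in_contact] - t_to))
  v_g <- c(contact[seq_len(n_pre), 3], rep(v_to, sum(!in_contact)))
  if (rigid) {
    s_p <- v_p <- numeric(length(frame_times))
    diss <- numeric(length(frame_times))
    wall_j <- c(contact[seq_len(n_pre), 7], rep(final[6], sum(!in_contact)))
    s_p_to <- 0; v_p_to <- 0
  } else {
    # platform rings on freely after separation (undriven damped oscillator)
    s_p_to <- final[3]
    v_p_to <- final[4]
    post <- free_platform(frame_times[!in_contact] - t_to, s_p_to, v_p_to,
                          k_p, m_p, c_p)
    s_p <- c(contact[seq_len(n_pre), 4], post$s)
    v_p <- c(contact[seq_len(n_pre), 5], post$v)
    diss <- c(contact[seq_len(n_pre), 6], rep(final[5], sum(!in_contact)))
    wall_j <- c(contact[seq_len(n_pre), 7], rep(final[6], sum(!in_contact)))
  }
  e <- pmin(s_g - s_p, x_true)
  ledger <- data.frame(
    time = frame_times,
    leg_pe = 0.5 * k_g * (x_true - e)^2 * (frame_times < t_to),
    jumper_ke = 0.5 * m_g * v_g^2,
    platform_pe = if (rigid) 0 else 0.5 * k_p * s_p^2,
    platform_ke = if (rigid) 0 else 0.5 * m_p * v_p^2,
    dissipated = diss
  )
  ledger$total <- with(ledger,
                       leg_pe + jumper_ke + platform_pe + platform_ke +
                         dissipated)
  # post-separation ring-down energy leaves the jumper's ledger scope: total
  # is tracked through separation, then platform terms evolve freely
  frames <- data.frame(time = frame_times, s_g = s_g, v_g = v_g,
                       s_p = s_p, v_p = v_p)

  # event log: platform maximally displaced where s_p is most negative
  if (rigid || n_pre == 0L) {
    t_maxdisp <- 0; max_disp <- 0; recoil <- FALSE
  } else {
    contact_sp <- c(contact[seq_len(n_pre), 4], s_p_to)
    contact_t <- c(contact[seq_len(n_pre), 1], t_to)
    i_min <- which.min(contact_sp)
    t_maxdisp <- contact_t[i_min]
    max_disp <- -contact_sp[i_min]
    recoil <- (t_maxdisp < t_to) && (v_p_to > 0)
  }
  theta <- config$elevation_deg * pi / 180
  momentum_residual <- m_g * v_to +
    (if (rigid) 0 else m_p * v_p_to) - final[6]
  structure(
    list(
      frames = frames, ledger = ledger,
      takeoff_time = t_to,
      takeoff_speed = unname(v_to),
      takeoff_velocity = unname(v_to) * c(cos(theta), sin(theta)),
      takeoff_position = unname(s_g_to),
      max_displacement_time = unname(t_maxdisp),
      max_platform_displacement = unname(max_disp),
      recoil_before_takeoff = recoil,
      platform_velocity_at_takeoff = unname(if (rigid) 0 else v_p_to),
      momentum_residual = unname(momentum_residual),
      initial_energy = 0.5 * k_g * x_true^2,
      config = config
    ),
    class = "sim_result"
  )
}

# closed-form free response of the damped platform mode after separation
free_platform <- function(t, s0, v0, k, m, c) {
  if (length(t) == 0L) return(list(s = numeric(0), v = numeric(0)))
  wn <- sqrt(k / m)
  zeta <- c / (2 * sqrt(k * m))
  if (zeta < 1) {
    wd <- wn * sqrt(1 - zeta^2)
    A <- s0
    B <- (v0 + zeta * wn * s0) / wd
    env <- exp(-zeta * wn * t)
    s <- env * (A * cos(wd * t) + B * sin(wd * t))
    v <- env * ((B * wd - A * zeta * wn) * cos(wd * t) -
                  (A * wd + B * zeta * wn) * sin(wd * t))
  } else {
    r1 <- -wn * (zeta - sqrt(zeta^2 - 1))
    r2 <- -wn * (zeta + sqrt(zeta^2 - 1))
    A <- (v0 - r2 * s0) / (r1 - r2)
    B <- s0 - A
    s <- A * exp(r1 * t) + B * exp(r2 * t)
    v <- A * r1 * exp(r1 * t) + B * r2 * exp(r2 * t)
  }
  list(s = s, v = v)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    paste0("Simulated jump: take-off at %.4f s, speed %.4f m/s\n",
           "  max platform displacement %.4g m at %.4f s; recoil before ",
           "take-off: %s\n"),
    x$takeoff_time, x$takeoff_speed, x$max_platform_displacement,
    x$max_displacement_time, x$recoil_before_takeoff
  ))
  invisible(x)
}

#' Render a simulated jump as a digitized recording
#'
#' Emulates the video digitization of a real jump: samples the simulated
#' body landmark and platform tarsus point at the camera frame rate, adds
#' independent Gaussian noise (s.d. `noise_sd`) to every coordinate, and
#' assembles a [jump_recording()] with the first-movement and last-contact
#' frame anchors a human digitizer would mark. The 2-D positions place the
#' origin at the undeflected platform surface beneath the animal, +x in the
#' jump direction, +y up; body and platform displacements act along the
#' thrust axis at the configured elevation.
#'
#' @param result a [simulate_jump()] result.
#' @param config the [sim_config()] used (defaults to the one stored in
#'   `result`).
#' @param animal_id,platform_id,line_index identifiers for the recording.
#' @param fixed_end_distance distance from the animal to the platform's
#'   fixed end, m.
#' @return List with the `recording` (a [jump_recording()]) and `truth`
#'   (take-off speed/time, stroke, stiffness, elevation actually simulated).
#' @export
render_recording <- function(result, config = result$config,
                             animal_id = "sim", platform_id = "control",
                             line_index = NA_integer_,
                             fixed_end_distance = 0.30) {
  stopifnot(inherits(result, "sim_result"))
  fps <- config$frame_rate
  window <- as.integer(round(0.010 * fps))
  last_contact <- floor(result$takeoff_time * fps)
  frames <- result$frames
  need_frames <- 0:(last_contact + window)
  if (max(need_frames) + 1L > nrow(frames))
    stop("simulation too short to cover last contact + 10 ms")
  theta <- config$elevation_deg * pi / 180
  dir <- c(cos(theta), sin(theta))
  idx <- need_frames + 1L
  if (config$noise_sd > 0) set.seed(config$seed)
  noise <- function(n) {
    if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else
      numeric(n)
  }
  bx <- frames$s_g[idx] * dir[1] + noise(length(idx))
  by <- frames$s_g[idx] * dir[2] + noise(length(idx))
  body <- tracked_series(need_frames, bx, by, frame_rate = fps,
                         calibrated = TRUE)
  tarsus <- NULL
  if (platform_id != "control") {
    t_idx <- c(1L, last_contact + 1L)
    tx <- frames$s_p[t_idx] * dir[1] + noise(2)
    ty <- frames$s_p[t_idx] * dir[2] + noise(2)
    tarsus <- tracked_series(c(0L, last_contact), tx, ty, frame_rate = fps,
                             calibrated = TRUE)
  }
  rec <- jump_recording(
    body_series = body, tarsus_series = tarsus,
    first_movement_frame = 0L, last_contact_frame = last_contact,
    animal_id = animal_id, platform_id = platform_id,
    line_index = line_index, fixed_end_x = -fixed_end_distance
  )
  list(
    recording = rec,
    truth = list(
      takeoff_speed = result$takeoff_speed,
      takeoff_time = result$takeoff_time,
      k_g_true = config$k_g_true,
      x_true = config$x_true,
      elevation_deg = config$elevation_deg,
      max_platform_displacement = result$max_platform_displacement,
      recoil_before_takeoff = result$recoil_before_takeoff
    )
  )
}

#' Sweep platform stiffness and mass
#'
#' Simulates the jump over a grid of platform stiffnesses and effective
#' masses and tabulates relative take-off performance against the rigid
#' limit: relative speed, relative kinetic energy, and whether the platform
#' recoiled before separation (the energy-recovery signature).
#'
#' @param base a [sim_config()]; its jumper parameters are held fixed.
#' @param k_p_values platform stiffness grid, N m^-1.
#' @param m_p_values effective platform mass grid, kg.
#' @return Data frame: `k_p`, `m_p_eff`, `k_ratio` (k_g/k_p), `m_ratio`
#'   (m_g/m_p), `rel_speed`, `rel_KE`, `recoil_before_takeoff`,
#'   `takeoff_time`.
#' @export
sweep_platforms <- function(base, k_p_values, m_p_values) {
  stopifnot(inherits(base, "sim_config"))
  if (length(k_p_values) == 0L || length(m_p_values) == 0L)
    stop("stiffness and mass grids must be non-empty")
  v_rigid <- spring_launch_speed(base$k_g_true, base$m_g, base$x_true)
  grid <- expand.grid(k_p = k_p_values, m_p_eff = m_p_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- sim_config(
      m_g = base$m_g, k_g_true = base$k_g_true, x_true = base$x_true,
      elevation_deg = base$elevation_deg,
      m_p_eff = grid$m_p_eff[i], k_p = grid$k_p[i],
      platform_damping_ratio = base$platform_damping_ratio,
      frame_rate = base$frame_rate, noise_sd = 0, seed = base$seed,
      rtol = base$rtol, atol = base$atol
    )
    res <- simulate_jump(cfg)
    data.frame(
      k_p = grid$k_p[i], m_p_eff = grid$m_p_eff[i],
      k_ratio = stiffness_ratio(base$k_g_true, grid$k_p[i]),
      m_ratio = mass_ratio(base$m_g, grid$m_p_eff[i]),
      rel_speed = res$takeoff_speed / v_rigid,
      rel_KE = (res$takeoff_speed / v_rigid)^2,
      recoil_before_takeoff = res$recoil_before_takeoff,
      takeoff_time = res$takeoff_time
    )
  })
  do.call(rbind, rows)
}
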