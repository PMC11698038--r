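# Shared fixture builders: everything is constructed in code at test time.

# A minimal calibrated recording with the body landmark on a straight line:
# position p0 at the last-contact frame, p1 ten frames later.
make_chord_recording <- function(p0, p1, last_contact = 28L,
                                 first_movement = 0L, frame_rate = 1000,
                                 tarsus = NULL, fixed_end_x = -0.30,
                                 platform_id = "control",
                                 line_index = NA_integer_) {
  frames <- 0:(last_contact + 10L)
  # linear motion through p0 at last_contact and p1 ten frames later
  fr <- (frames - last_contact) / 10
  body <- tracked_series(
    frames,
    p0[1] + fr * (p1[1] - p0[1]),
    p0[2] + fr * (p1[2] - p0[2]),
    frame_rate = frame_rate, calibrated = TRUE
  )
  tarsus_series <- NULL
  if (!is.null(tarsus)) {
    tarsus_series <- tracked_series(
      c(first_movement, last_contact),
      c(tarsus$from[1], tarsus$to[1]),
      c(tarsus$from[2], tarsus$to[2]),
      frame_rate = frame_rate, calibrated = TRUE
    )
  }
  jump_recording(
    body_series = body, tarsus_series = tarsus_series,
    first_movement_frame = first_movement, last_contact_frame = last_contact,
    animal_id = "test", platform_id = platform_id, line_index = line_index,
    fixed_end_x = fixed_end_x
  )
}

# The cohort-mean morphometrics used throughout the worked examples.
mean_morph <- function() {
  morphometrics(body_mass = 1.13e-3, tibia_length = 15.6e-3,
                takeoff_angle_deg = 113)
}

# Synthetic normalized-jump data with a known platform-stiffness slope and
# per-animal random intercepts: the generate-then-refit oracle for the
# mixed models.
make_slope_data <- function(slope, intercept = 0.2, n_animals = 6,
                            k_p = seq(1, 3, length.out = 8),
                            sd_animal = 0.05, sd_resid = 0.05,
                            regime = "compliant", seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_animals), function(i) {
    a_i <- rnorm(1, 0, sd_animal)
    data.frame(
      animal_id = sprintf("a%02d", i),
      platform_id = "A",
      line_index = seq_along(k_p),
      k_p_N_m = k_p,
      regime = regime,
      rel_velocity = intercept + slope * k_p + a_i +
        rnorm(length(k_p), 0, sd_resid),
      stringsAsFactors = FALSE
    )
  }))
  rows
}
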