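#' Generate a synthetic jumping study
#'
#' Emulates the full experimental design as a simulation: a cohort of
#' spring-actuated jumpers, each recorded over three control jumps from a
#' rigid surface, ten jumps along the long compliant platform (A) and two
#' jumps from the short stiff platform (B), filmed at 1000 frames per
#' second with additive Gaussian digitization noise.
#'
#' Animal-level parameters are drawn once per animal around the cohort
#' means (body mass 1.13 g, tibia 15.6 mm, take-off joint angle 113
#' degrees, take-off elevation 43.5 degrees), with between-animal standard
#' deviations consistent with the cohort dispersion those means were
#' reported with. Jump-to-jump variation enters through a small stroke
#' jitter and the digitization noise. Platform stiffness profiles come
#' from cantilever beam theory via [synthetic_stiffness_profile()], with a
#' board modulus chosen so the profiles span ~0.3x to ~300x the jumper
#' stiffness (the effective modulus is below handbook basswood, absorbing
#' support compliance).
#'
#' @param n_animals number of animals in the cohort.
#' @param n_control control jumps per animal.
#' @param lines_A,lines_B line indices jumped on each platform.
#' @param noise_sd digitization noise s.d. per coordinate, m.
#' @param stroke_jitter_cv jump-to-jump coefficient of variation of the
#'   leg-spring stroke.
#' @param seed RNG seed.
#' @param elastic_modulus effective board modulus, Pa.
#' @param platform_B_only_animals if `TRUE`, half the animals jump platform
#'   A and half platform B (as in a two-group design); otherwise every
#'   animal jumps both.
#' @return List: `recordings` (list of [jump_recording()]), `truths`
#'   (matching list of simulator ground truths), `morphometrics` (named
#'   list per animal), `profiles` (stiffness profiles for A and B),
#'   `animals` (data frame of true per-animal parameters).
#' @export
synthetic_study <- function(n_animals = 5, n_control = 3,
                            lines_A = 1:10, lines_B = 1:2,
                            noise_sd = 1e-4, stroke_jitter_cv = 0.02,
                            seed = 1L, elastic_modulus = 2.6e9,
                            platform_B_only_animals = FALSE) {
  set.seed(seed)
  platA <- platform_spec(length = 0.61, width = 0.025, thickness = 0.002,
                         total_mass = 6.34e-3,
                         elastic_modulus = elastic_modulus)
  platB <- platform_spec(length = 0.124, width = 0.025, thickness = 0.002,
                         total_mass = 1.01e-3,
                         elastic_modulus = elastic_modulus)
  prof_A <- synthetic_stiffness_profile(platA, n_lines = 10, platform_id = "A")
  prof_B <- synthetic_stiffness_profile(platB, n_lines = 2, platform_id = "B")

  # cohort-level dispersion: s.d. = s.e.m. x sqrt(n) at the reported n = 40
  sd_mass <- 0.04e-3 * sqrt(40)
  sd_tibia <- 0.187e-3 * sqrt(40)
  sd_alpha <- 2 * sqrt(40)
  animals <- data.frame(
    animal_id = sprintf("gh%02d", seq_len(n_animals)),
    body_mass = pmax(stats::rnorm(n_animals, 1.13e-3, sd_mass), 0.5e-3),
    tibia_length = pmax(stats::rnorm(n_animals, 15.6e-3, sd_tibia), 8e-3),
    takeoff_angle_deg = pmin(pmax(
      stats::rnorm(n_animals, 113, sd_alpha), 60), 170),
    elevation_deg = pmin(pmax(stats::rnorm(n_animals, 43.5, 5), 19), 69),
    k_g_true = pmax(stats::rnorm(n_animals, 3.42, 0.11 * sqrt(40)), 1),
    stringsAsFactors = FALSE
  )
  morph <- lapply(seq_len(n_animals), function(i) {
    morphometrics(
      body_mass = animals$body_mass[i],
      tibia_length = animals$tibia_length[i],
      takeoff_angle_deg = animals$takeoff_angle_deg[i]
    )
  })
  names(morph) <- animals$animal_id

  recordings <- list()
  truths <- list()
  add_jump <- function(i, platform_id, line_index) {
    m <- morph[[i]]
    x0 <- acceleration_distance(m)
    x_jump <- x0 * exp(stats::rnorm(1, 0, stroke_jitter_cv))
    if (platform_id == "control") {
      k_p <- Inf; m_p <- Inf
    } else {
      prof <- if (platform_id == "A") prof_A else prof_B
      k_p <- prof$k_N_per_m[prof$line_index == line_index]
      m_p <- prof$m_p_eff_kg[prof$line_index == line_index]
    }
    cfg <- sim_config(
      m_g = animals$body_mass[i], k_g_true = animals$k_g_true[i],
      x_true = x_jump, elevation_deg = animals$elevation_deg[i],
      m_p_eff = m_p, k_p = k_p, noise_sd = noise_sd,
      seed = sample.int(.Machine$integer.max, 1)
    )
    res <- simulate_jump(cfg)
    d <- if (platform_id == "control") 0.30 else 0.05 * line_index
    rr <- render_recording(res, cfg, animal_id = animals$animal_id[i],
                           platform_id = platform_id,
                           line_index = line_index,
                           fixed_end_distance = max(d, 0.05))
    recordings[[length(recordings) + 1L]] <<- rr$recording
    truths[[length(truths) + 1L]] <<- rr$truth
  }
  for (i in seq_len(n_animals)) {
    for (j in seq_len(n_control)) add_jump(i, "control", NA_integer_)
    does_A <- !platform_B_only_animals || i <= ceiling(n_animals / 2)
    does_B <- !platform_B_only_animals || i > ceiling(n_animals / 2)
    if (does_A) for (ln in sample(lines_A)) add_jump(i, "A", ln)
    if (does_B) for (ln in sample(lines_B)) add_jump(i, "B", ln)
  }
  list(recordings = recordings, truths = truths, morphometrics = morph,
       profiles = rbind(as.data.frame(prof_A), as.data.frame(prof_B)),
       animals = animals)
}

#' Build the canonical jump table from recordings
#'
#' Runs the kinematic and energetic extraction over a set of recordings,
#' looking up each jump's platform stiffness and effective tip mass in the
#' stiffness profiles.
#'
#' @param recordings list of [jump_recording()].
#' @param morphometrics named list of [morphometrics()], indexed by
#'   `animal_id`.
#' @param profiles stiffness profile data frame (`platform_id`,
#'   `line_index`, `k_N_per_m`, optionally `m_p_eff_kg`).
#' @return The canonical jump table: one row per jump.
#' @export
extract_jump_table <- function(recordings, morphometrics, profiles = NULL) {
  rows <- lapply(recordings, function(rec) {
    m <- morphometrics[[rec$animal_id]]
    if (is.null(m))
      stop("no morphometrics for animal ", rec$animal_id)
    k_p <- NA_real_; m_p <- NA_real_
    if (rec$platform_id != "control") {
      if (is.null(profiles))
        stop("experimental jump for ", rec$animal_id,
             " but no stiffness profiles supplied")
      hit <- profiles$platform_id == rec$platform_id &
        profiles$line_index == rec$line_index
      if (!any(hit))
        stop("no stiffness calibration for platform ", rec$platform_id,
             " line ", rec$line_index)
      k_p <- profiles$k_N_per_m[hit][1]
      if ("m_p_eff_kg" %in% names(profiles))
        m_p <- profiles$m_p_eff_kg[hit][1]
    }
    jump_variables(rec, m, k_p = k_p, m_p = m_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
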