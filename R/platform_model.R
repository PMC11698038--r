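#' Standard gravity used throughout the package
#' @return 9.81 m s^-2
#' @export
standard_gravity <- function() 9.81

#' Platform stiffness from a load-deflection calibration
#'
#' Each marked line on a cantilever platform is calibrated by hanging known
#' masses at the line and measuring the static deflection. Each (mass,
#' deflection) entry gives one stiffness estimate k_i = m_i g / delta_i;
#' entries are combined by averaging those per-entry estimates (the default,
#' robust to one bad entry) or by a least-squares fit of force on deflection
#' through the origin.
#'
#' @param entries data frame or list with numeric fields `applied_mass`
#'   (kg) and `deflection` (m), one row per calibration weight.
#' @param method `"mean"` (average of per-entry k) or `"ls"` (least squares
#'   through the origin).
#' @param g gravitational acceleration, m s^-2.
#' @return Stiffness in N m^-1.
#' @export
stiffness_from_load_deflection <- function(entries, method = c("mean", "ls"),
                                           g = standard_gravity()) {
  method <- match.arg(method)
  entries <- as.data.frame(entries)
  if (!all(c("applied_mass", "deflection") %in% names(entries)))
    stop("entries need applied_mass (kg) and deflection (m) fields")
  if (nrow(entries) < 1L) stop("need at least one load-deflection entry")
  if (any(!is.finite(entries$deflection)) || any(entries$deflection <= 0))
    stop("deflections must be positive and finite")
  if (any(entries$applied_mass <= 0))
    stop("applied masses must be positive")
  force <- entries$applied_mass * g
  switch(method,
    mean = mean(force / entries$deflection),
    ls = sum(force * entries$deflection) / sum(entries$deflection^2)
  )
}

#' Build a stiffness profile from a platform calibration table
#'
#' Takes the long-format calibration table (one row per line per weight) and
#' returns per-line stiffness with the line's distance from the fixed end.
#' Lines are spaced `line_spacing` apart starting at `line_spacing` from the
#' fixed end; line 1 is the stiffest (closest to the support), and the
#' profile must decrease monotonically along the board.
#'
#' @param calib data frame with columns `platform_id`, `line_index`,
#'   `applied_mass` (kg), `deflection` (m).
#' @param line_spacing distance between marked lines, metres (default
#'   0.05).
#' @param method passed to [stiffness_from_load_deflection()].
#' @return A `stiffness_profile` data frame: `platform_id`, `line_index`,
#'   `position_m`, `k_N_per_m`.
#' @export
stiffness_profile <- function(calib, line_spacing = 0.05,
                              method = c("mean", "ls")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(calib))
  need <- c("platform_id", "line_index", "applied_mass", "deflection")
  if (!all(need %in% names(calib)))
    stop("calibration table needs columns ", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(
    split(calib, list(calib$platform_id, calib$line_index), drop = TRUE),
    function(d) {
      data.frame(
        platform_id = d$platform_id[1],
        line_index = as.integer(d$line_index[1]),
        position_m = d$line_index[1] * line_spacing,
        k_N_per_m = stiffness_from_load_deflection(d, method = method)
      )
    }
  ))
  out <- out[order(out$platform_id, out$line_index), ]
  rownames(out) <- NULL
  for (pid in unique(out$platform_id)) {
    k <- out$k_N_per_m[out$platform_id == pid]
    if (any(k <= 0)) stop("non-positive stiffness in profile for platform ", pid)
    if (any(diff(k) >= 0))
      stop("stiffness must decrease strictly with distance from the fixed ",
           "end (platform ", pid, ")")
  }
  class(out) <- c("stiffness_profile", "data.frame")
  out
}

#' Specification of a (synthetic) cantilever platform
#'
#' @param length,width,thickness board dimensions, metres.
#' @param total_mass board mass, kg.
#' @param elastic_modulus Young's modulus, Pa (synthetic boards only; real
#'   boards are calibrated empirically).
#' @return A `platform_spec` list.
#' @export
platform_spec <- function(length, width, thickness, total_mass,
                          elastic_modulus = 10e9) {
  vals <- c(length, width, thickness, total_mass, elastic_modulus)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all platform dimensions, mass and modulus must be positive")
  structure(
    list(length = length, width = width, thickness = thickness,
         total_mass = total_mass, elastic_modulus = elastic_modulus),
    class = "platform_spec"
  )
}

#' Tip stiffness of an end-loaded cantilever
#'
#' Euler-Bernoulli result for a rectangular-section cantilever loaded at the
#' free end: k = 3 E I / L^3 with I = b h^3 / 12. Used to generate realistic
#' synthetic stiffness profiles; real platforms are calibrated by
#' load-deflection measurement instead.
#'
#' @param E Young's modulus, Pa.
#' @param width,thickness section dimensions b and h, metres.
#' @param free_length overhanging length L, metres.
#' @return Tip stiffness in N m^-1.
#' @export
cantilever_tip_stiffness <- function(E, width, thickness, free_length) {
  vals <- c(E, width, thickness, free_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("modulus, section dimensions and free length must all be positive")
  I <- width * thickness^3 / 12
  3 * E * I / free_length^3
}

#' Effective tip mass of the overhanging cantilever portion
#'
#' Lumps the distributed board into an equivalent point mass at the tip so
#' the simulator can treat the platform as a spring-mass. The first-mode
#' Rayleigh lumping for a uniform end-loaded cantilever assigns 33/140 of
#' the overhanging mass to the tip.
#'
#' @param platform a [platform_spec()].
#' @param free_length overhanging length, metres (<= platform length).
#' @param coefficient lumping coefficient; 33/140 by default.
#' @return Effective tip mass, kg.
#' @export
effective_tip_mass <- function(platform, free_length,
                               coefficient = 33 / 140) {
  stopifnot(inherits(platform, "platform_spec"))
  if (free_length < 0 || free_length > platform$length)
    stop("free_length must lie within [0, platform length]")
  overhang_mass <- platform$total_mass * free_length / platform$length
  coefficient * overhang_mass
}

#' Generate a synthetic stiffness profile from beam theory
#'
#' @param platform a [platform_spec()].
#' @param line_spacing line spacing, metres.
#' @param n_lines number of marked lines.
#' @param platform_id label for the output rows.
#' @return A `stiffness_profile` data frame with an extra `m_p_eff_kg`
#'   column (effective tip mass at each line's free length).
#' @export
synthetic_stiffness_profile <- function(platform, line_spacing = 0.05,
                                        n_lines = 10, platform_id = "A") {
  position <- line_spacing * seq_len(n_lines)
  if (max(position) > platform$length)
    stop("lines extend beyond the platform length")
  out <- data.frame(
    platform_id = platform_id,
    line_index = seq_len(n_lines),
    position_m = position,
    k_N_per_m = cantilever_tip_stiffness(platform$elastic_modulus,
                                         platform$width, platform$thickness,
                                         position),
    m_p_eff_kg = vapply(position, function(L) effective_tip_mass(platform, L),
                        numeric(1))
  )
  class(out) <- c("stiffness_profile", "data.frame")
  out
}

#' Jumper-over-platform stiffness and mass ratios
#'
#' The two dimensionless numbers that govern energy exchange with the
#' substrate: the jumper's effective spring stiffness over the platform
#' stiffness, and the jumper's mass over the platform mass. Energy recovery
#' from substrate recoil requires a stiff, light platform (stiffness ratio
#' < 1 at a sufficiently small mass ratio).
#'
#' @param k_g,k_p jumper and platform stiffness, N m^-1.
#' @param m_g,m_p jumper and platform mass, kg.
#' @return Dimensionless ratio.
#' @export
stiffness_ratio <- function(k_g, k_p) {
  if (any(k_p <= 0)) stop("platform stiffness must be positive")
  k_g / k_p
}

#' @rdname stiffness_ratio
#' @export
mass_ratio <- function(m_g, m_p) {
  if (any(m_p <= 0)) stop("platform mass must be positive")
  m_g / m_p
}

#' Read / write platform calibration and stiffness-profile CSVs
#'
#' The calibration CSV uses field units (`applied_mass_g`, `deflection_mm`)
#' as written at the bench; reading converts to SI.
#'
#' @param path CSV path.
#' @return `read_load_deflection` returns a data frame with `platform_id`,
#'   `line_index`, `applied_mass` (kg), `deflection` (m).
#' @export
read_load_deflection <- function(path) {
  if (!file.exists(path)) stop("no such calibration table: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("platform_id", "line_index", "applied_mass_g", "deflection_mm")
  if (!all(need %in% names(d)))
    stop("calibration CSV needs columns ", paste(need, collapse = ", "))
  data.frame(
    platform_id = as.character(d$platform_id),
    line_index = as.integer(d$line_index),
    applied_mass = d$applied_mass_g / 1000,
    deflection = d$deflection_mm / 1000
  )
}

#' @rdname read_load_deflection
#' @param profile a `stiffness_profile` data frame.
#' @export
write_stiffness_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
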