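#' Construct a tracked landmark series
#'
#' A tracked series is the time-stamped planar trajectory of a single
#' digitized landmark: one row per video frame, with frame index, time in
#' seconds, and x/y coordinates. Coordinates are in pixels as exported by the
#' digitization software until [calibrate()] converts them to metres.
#'
#' Frames missing from the export are preserved as gaps (absent rows), never
#' interpolated: downstream code that needs a specific frame fails loudly if
#' it is not present.
#'
#' @param frame integer vector of frame indices, >= 0, strictly increasing.
#' @param x,y numeric coordinate vectors, same length as `frame`.
#' @param frame_rate frames per second (> 0); time is `frame / frame_rate`.
#' @param calibrated logical; `TRUE` once coordinates are in metres.
#' @return A `tracked_series` object (a data frame with columns `frame`,
#'   `time`, `x`, `y` and attributes `frame_rate`, `calibrated`).
#' @export
tracked_series <- function(frame, x, y, frame_rate = 1000, calibrated = FALSE) {
  frame <- as.integer(frame)
  if (length(frame) == 0L) stop("tracked series must contain at least one frame")
  if (length(x) != length(frame) || length(y) != length(frame))
    stop("frame, x and y must have equal length")
  if (anyNA(frame) || any(frame < 0L))
    stop("frame indices must be non-negative integers")
  if (any(diff(frame) <= 0L))
    stop("frame indices must be strictly increasing (duplicate or out-of-order frame)")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  ts <- data.frame(
    frame = frame,
    time = frame / frame_rate,
    x = as.numeric(x),
    y = as.numeric(y)
  )
  attr(ts, "frame_rate") <- frame_rate
  attr(ts, "calibrated") <- isTRUE(calibrated)
  class(ts) <- c("tracked_series", "data.frame")
  ts
}

#' @export
print.tracked_series <- function(x, ...) {
  cat(sprintf(
    "Tracked series: %d frames at %g fps (%s)\n",
    nrow(x), attr(x, "frame_rate"),
    if (attr(x, "calibrated")) "metres" else "pixels"
  ))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a digitization-software coordinate export
#'
#' Parses the delimited text exported by video digitization tools: a header
#' row naming frame (or `t`), `x` and `y` columns, one row per digitized
#' frame. Both comma- and tab-delimited dialects are accepted, as is a
#' decimal-comma dialect (`dec = ","`). Coordinates are returned in pixel
#' space; apply [calibrate()] with the ruler-derived scale to obtain metres.
#'
#' @param path path to the export file.
#' @param frame_rate recording frame rate in frames per second.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param dec decimal mark, `"."` (default) or `","`.
#' @return An uncalibrated [tracked_series()].
#' @export
read_tracker_export <- function(path, frame_rate = 1000, sep = ",", dec = ".") {
  if (!file.exists(path)) stop("no such tracker export: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                      strip.white = TRUE, blank.lines.skip = TRUE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  names(raw) <- tolower(names(raw))
  if (!all(c("x", "y") %in% names(raw)))
    stop("tracker export must have x and y columns: ", path)
  if ("frame" %in% names(raw)) {
    frame <- raw$frame
  } else if ("t" %in% names(raw)) {
    # a time-only export: recover frame indices from the time stamps
    frame <- round(raw$t * frame_rate)
    if (any(abs(raw$t * frame_rate - frame) > 1e-6))
      stop("time stamps in ", path, " are not integral frames at ",
           frame_rate, " fps")
  } else {
    stop("tracker export must have a frame or t column: ", path)
  }
  x <- suppressWarnings(as.numeric(as.character(raw$x)))
  y <- suppressWarnings(as.numeric(as.character(raw$y)))
  frame <- suppressWarnings(as.numeric(as.character(frame)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(frame))
  if (length(bad))
    stop("malformed row in ", path, " at line ", bad[1] + 1L,
         " (non-numeric or missing value)")
  tracked_series(frame, x, y, frame_rate = frame_rate)
}

#' Write a tracked series in the export format `read_tracker_export` reads
#'
#' @param series a [tracked_series()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_tracker_export <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "tracked_series"))
  out <- data.frame(frame = series$frame, t = series$time,
                    x = series$x, y = series$y)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a pixel-space series to metres
#'
#' Each video is calibrated against a ruler of known length in the camera
#' view; `scale` is metres per pixel from that ruler. Calibration multiplies
#' coordinates only; frame indices and times are untouched. Calibration is
#' linear, so calibrating with `a * b` equals calibrating with `a` then `b`.
#'
#' @param series a [tracked_series()].
#' @param scale metres per pixel (> 0).
#' @return The calibrated series.
#' @export
calibrate <- function(series, scale) {
  stopifnot(inherits(series, "tracked_series"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a single positive number (metres per pixel)")
  series$x <- series$x * scale
  series$y <- series$y * scale
  attr(series, "calibrated") <- TRUE
  series
}

#' Ruler-based scale factor
#'
#' @param ruler_length_m physical ruler length in metres (e.g. 0.30).
#' @param ruler_length_px ruler length in image pixels.
#' @return metres per pixel.
#' @export
ruler_scale <- function(ruler_length_m, ruler_length_px) {
  if (ruler_length_m <= 0 || ruler_length_px <= 0)
    stop("ruler lengths must be positive")
  ruler_length_m / ruler_length_px
}

#' Assemble a calibrated jump recording
#'
#' A jump recording bundles everything digitized for one jump: the body
#' landmark trajectory (metathoracic leg joint or pronotum tip, whichever
#' stayed visible), the two platform tarsus points (digitized beneath the
#' left tarsus at the first frame of visible metathoracic movement and at
#' the last frame of tarsi-platform contact), and the frame anchors those
#' two events define. Coordinates follow the pipeline convention: +x is the
#' jump direction, +y is up, origin at the undeflected platform surface
#' beneath the animal.
#'
#' The body series must cover the last-contact frame and the frame 10 ms
#' later (the take-off velocity chord). At frame rates other than 1000 fps
#' the 10 ms window must still be an integer number of frames.
#'
#' @param body_series calibrated [tracked_series()] of the body landmark.
#' @param tarsus_series calibrated [tracked_series()] of exactly two points:
#'   the platform tarsus position at first movement and at last contact.
#'   May be `NULL` for control (rigid-platform) jumps.
#' @param first_movement_frame first frame of visible metathoracic movement.
#' @param last_contact_frame last frame of tarsi-platform contact.
#' @param animal_id,platform_id identifiers; `platform_id` is one of
#'   `"control"`, `"A"`, `"B"`.
#' @param line_index platform line number 1-10, or `NA` for control.
#' @param fixed_end_x x coordinate of the platform's fixed-end reference
#'   (metres); used to construct the deformed platform plane.
#' @param landmark which body landmark was digitized (recorded, not
#'   corrected for: no centre-of-mass offset is applied).
#' @return A `jump_recording` object (a list).
#' @export
jump_recording <- function(body_series, tarsus_series = NULL,
                           first_movement_frame, last_contact_frame,
                           animal_id, platform_id = "control",
                           line_index = NA_integer_, fixed_end_x = NA_real_,
                           landmark = c("joint", "pronotum")) {
  stopifnot(inherits(body_series, "tracked_series"))
  landmark <- match.arg(landmark)
  if (!attr(body_series, "calibrated"))
    stop("body_series must be calibrated to metres first")
  frame_rate <- attr(body_series, "frame_rate")
  window <- 0.010 * frame_rate
  if (abs(window - round(window)) > 1e-9)
    stop("the 10 ms take-off window is not an integer frame count at ",
         frame_rate, " fps")
  window <- as.integer(round(window))
  first_movement_frame <- as.integer(first_movement_frame)
  last_contact_frame <- as.integer(last_contact_frame)
  if (first_movement_frame > last_contact_frame)
    stop("first_movement_frame must not exceed last_contact_frame")
  need <- c(last_contact_frame, last_contact_frame + window)
  missing <- setdiff(need, body_series$frame)
  if (length(missing))
    stop("body series is missing required frame(s) ",
         paste(missing, collapse = ", "),
         " (last contact and 10 ms later must be digitized, not interpolated)")
  if (!is.null(tarsus_series)) {
    stopifnot(inherits(tarsus_series, "tracked_series"))
    if (!attr(tarsus_series, "calibrated"))
      stop("tarsus_series must be calibrated to metres first")
    if (nrow(tarsus_series) != 2L)
      stop("tarsus_series must contain exactly 2 points ",
           "(first movement and last contact)")
  }
  platform_id <- as.character(platform_id)
  if (!platform_id %in% c("control", "A", "B"))
    stop("platform_id must be one of control, A, B")
  if (platform_id != "control" && is.na(line_index))
    stop("experimental jumps need a line_index")
  structure(
    list(
      body_series = body_series,
      tarsus_series = tarsus_series,
      frame_rate = frame_rate,
      takeoff_window_frames = window,
      first_movement_frame = first_movement_frame,
      last_contact_frame = last_contact_frame,
      animal_id = as.character(animal_id),
      platform_id = platform_id,
      line_index = as.integer(line_index),
      fixed_end_x = fixed_end_x,
      landmark = landmark
    ),
    class = "jump_recording"
  )
}

#' @export
print.jump_recording <- function(x, ...) {
  cat(sprintf(
    "Jump recording: animal %s, platform %s%s\n  frames %d (first movement) to %d (last contact), %g fps\n",
    x$animal_id, x$platform_id,
    if (is.na(x$line_index)) "" else paste0(" line ", x$line_index),
    x$first_movement_frame, x$last_contact_frame, x$frame_rate
  ))
  invisible(x)
}

#' Per-animal morphometrics
#'
#' Body mass, leg segment lengths and the femur-tibia joint angle at
#' take-off, plus the jumping-muscle mass used for the density quantities
#' (kinetic energy density, power density). Femur length defaults to tibia
#' length: grasshopper femora and tibiae are of similar length, so the leg
#' extension geometry is treated as an isosceles triangle. Muscle mass
#' defaults to `muscle_fraction * body_mass`; see [muscle_mass_default()]
#' for how the default fraction is derived.
#'
#' @param body_mass body mass in kg.
#' @param tibia_length tibia length in metres.
#' @param takeoff_angle_deg femur-tibia joint angle at take-off, degrees,
#'   in (0, 180).
#' @param femur_length femur length in metres; defaults to `tibia_length`.
#' @param muscle_mass jumping-muscle mass in kg; defaults to
#'   `muscle_fraction * body_mass`.
#' @param muscle_fraction muscle mass as a fraction of body mass, used only
#'   when `muscle_mass` is not given.
#' @return A `morphometrics` object (a list).
#' @export
morphometrics <- function(body_mass, tibia_length, takeoff_angle_deg,
                          femur_length = tibia_length, muscle_mass = NULL,
                          muscle_fraction = muscle_fraction_default()) {
  if (body_mass <= 0 || tibia_length <= 0 || femur_length <= 0)
    stop("masses and lengths must be positive")
  if (takeoff_angle_deg <= 0 || takeoff_angle_deg >= 180)
    stop("take-off joint angle must lie strictly between 0 and 180 degrees")
  if (is.null(muscle_mass)) muscle_mass <- muscle_fraction * body_mass
  if (muscle_mass <= 0) stop("muscle mass must be positive")
  structure(
    list(
      body_mass = body_mass,
      tibia_length = tibia_length,
      femur_length = femur_length,
      takeoff_angle_deg = takeoff_angle_deg,
      muscle_mass = muscle_mass
    ),
    class = "morphometrics"
  )
}

#' Write / read the canonical jump table
#'
#' The jump table is the pipeline's tabular interchange format: one row per
#' jump with identifiers (`animal_id`, `platform_id`, `line_index`) followed
#' by every derived variable in SI units. Numeric fields round-trip at full
#' double precision (17 significant digits).
#'
#' @param jump_table data frame of per-jump variables.
#' @param path CSV path.
#' @return `write_jump_table` returns `path` invisibly; `read_jump_table`
#'   returns the data frame.
#' @export
write_jump_table <- function(jump_table, path) {
  stopifnot(is.data.frame(jump_table))
  num <- vapply(jump_table, is.numeric, logical(1))
  out <- jump_table
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_jump_table
#' @export
read_jump_table <- function(path) {
  if (!file.exists(path)) stop("no such jump table: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
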