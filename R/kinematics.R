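deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

body_position_at <- function(recording, frame) {
  i <- match(frame, recording$body_series$frame)
  if (is.na(i))
    stop("body landmark not digitized at frame ", frame)
  c(x = recording$body_series$x[i], y = recording$body_series$y[i])
}

#' Take-off displacement chord over the 10 ms post-contact window
#'
#' The body landmark position at the last frame of tarsi-platform contact
#' and 10 ms later define the take-off displacement vector; its length over
#' 0.010 s is the take-off speed. No gravity correction is applied over the
#' window: gravity accounts for only 1-2% of the energy budget at these
#' masses and distances.
#'
#' @param recording a [jump_recording()].
#' @return `takeoff_displacement`: named vector `c(dx, dy)` in metres.
#' @export
takeoff_displacement <- function(recording) {
  stopifnot(inherits(recording, "jump_recording"))
  p0 <- body_position_at(recording, recording$last_contact_frame)
  p1 <- body_position_at(recording,
                         recording$last_contact_frame +
                           recording$takeoff_window_frames)
  c(dx = unname(p1["x"] - p0["x"]), dy = unname(p1["y"] - p0["y"]))
}

#' @rdname takeoff_displacement
#' @return `take_off_velocity`: speed in m s^-1.
#' @export
take_off_velocity <- function(recording) {
  d <- takeoff_displacement(recording)
  window_s <- recording$takeoff_window_frames / recording$frame_rate
  sqrt(sum(d^2)) / window_s
}

#' Time to take-off
#'
#' Elapsed time from the first frame of visible metathoracic movement to the
#' last frame of tarsi-platform contact.
#'
#' @param recording a [jump_recording()].
#' @return Time in seconds. A zero interval is returned with a warning.
#' @export
time_to_takeoff <- function(recording) {
  stopifnot(inherits(recording, "jump_recording"))
  nframes <- recording$last_contact_frame - recording$first_movement_frame
  if (nframes < 0) stop("first movement after last contact")
  if (nframes == 0)
    warning("zero-length take-off interval (first movement frame equals ",
            "last contact frame)")
  nframes / recording$frame_rate
}

#' Platform displacement and deformed-plane angle
#'
#' The tarsus point digitized on the platform at first movement and at last
#' contact measures how far the platform was driven during the jump. The
#' deformed platform plane is the line from the platform's fixed-end
#' reference to the displaced tarsus point; its angle to the horizontal
#' (negative when the board is pressed down) is used to express jump
#' elevation relative to the surface the animal actually left.
#'
#' @param recording a [jump_recording()]. Control jumps (no tarsus series)
#'   return zero displacement and a zero plane angle.
#' @return List with `displacement` (m) and `plane_angle_deg` (degrees).
#' @export
platform_displacement <- function(recording) {
  stopifnot(inherits(recording, "jump_recording"))
  if (is.null(recording$tarsus_series)) {
    return(list(displacement = 0, plane_angle_deg = 0))
  }
  ts <- recording$tarsus_series
  if (nrow(ts) != 2L)
    stop("tarsus series must contain exactly the first-movement and ",
         "last-contact points")
  disp <- sqrt((ts$x[2] - ts$x[1])^2 + (ts$y[2] - ts$y[1])^2)
  if (is.na(recording$fixed_end_x))
    stop("fixed-end reference needed to construct the deformed platform plane")
  dx <- ts$x[2] - recording$fixed_end_x
  dy <- ts$y[2]  # fixed end sits on the undeflected surface, y = 0
  if (dx <= 0)
    stop("displaced tarsus point must lie on the free side of the fixed end")
  list(displacement = disp, plane_angle_deg = rad2deg(atan2(dy, dx)))
}

#' Jump elevation relative to the deformed platform plane
#'
#' Angle between the take-off displacement vector and the deformed platform
#' plane, positive above the plane in the jump direction. Elevation is a
#' polar quantity: downstream normalization uses differences from the
#' control mean, not ratios.
#'
#' @param recording a [jump_recording()].
#' @param plane_angle_deg deformed-plane angle from
#'   [platform_displacement()]; defaults to computing it from the recording.
#' @return Elevation in degrees.
#' @export
elevation <- function(recording, plane_angle_deg = NULL) {
  d <- takeoff_displacement(recording)
  if (sqrt(sum(d^2)) == 0)
    stop("zero take-off displacement: elevation undefined")
  if (is.null(plane_angle_deg))
    plane_angle_deg <- platform_displacement(recording)$plane_angle_deg
  raw <- rad2deg(atan2(d["dy"], d["dx"])) - plane_angle_deg
  # map into (-180, 180]; jumps are forward so this lands in (-90, 180)
  unname((raw + 180) %% 360 - 180)
}

#' Acceleration distance from leg geometry (law of cosines)
#'
#' At the start of a jump the legs are fully flexed (tibia folded against
#' the femur); at take-off they are fully extended. The centre of mass
#' therefore accelerates over the distance spanned by the femur-tibia
#' triangle opening to the take-off joint angle alpha:
#' x = sqrt(Lf^2 + Lt^2 - 2 Lf Lt cos(alpha)).
#'
#' @param morph a [morphometrics()] object, or body-segment arguments.
#' @return Acceleration distance in metres.
#' @export
acceleration_distance <- function(morph) {
  stopifnot(inherits(morph, "morphometrics"))
  lf <- morph$femur_length
  lt <- morph$tibia_length
  a <- deg2rad(morph$takeoff_angle_deg)
  sqrt(lf^2 + lt^2 - 2 * lf * lt * cos(a))
}

#' Mean take-off acceleration
#'
#' Take-off velocity over time to take-off. This is the mean acceleration of
#' the launch, not the peak.
#'
#' @param v take-off velocity, m s^-1.
#' @param t time to take-off, s (> 0).
#' @return Acceleration in m s^-2.
#' @export
mean_acceleration <- function(v, t) {
  if (any(t <= 0)) stop("time to take-off must be positive")
  v / t
}
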