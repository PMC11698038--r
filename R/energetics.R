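#' Default jumping-muscle mass fraction
#'
#' Kinetic energy density and power density are expressed per unit of
#' jumping-muscle mass, which is not measured directly by the video
#' pipeline. The default fraction is back-solved from the control-jump
#' means: with take-off speed v and kinetic energy density KED both known
#' for control jumps, KED = (v^2 / 2) / f gives f = v^2 / (2 KED). At
#' v = 1.44 m s^-1 and KED = 24.79 J kg^-1 this yields f = 0.0418, i.e.
#' jumping muscle is ~4.2% of body mass (47.3 mg on a 1.13 g animal).
#'
#' @return The default muscle-mass fraction of body mass (dimensionless).
#' @export
muscle_fraction_default <- function() {
  0.5 * 1.44^2 / 24.79
}

#' @rdname muscle_fraction_default
#' @param body_mass body mass in kg.
#' @return `muscle_mass_default`: jumping-muscle mass in kg.
#' @export
muscle_mass_default <- function(body_mass) {
  muscle_fraction_default() * body_mass
}

#' Translational kinetic energy at take-off
#'
#' @param m_g jumper mass, kg.
#' @param v take-off speed, m s^-1.
#' @return Energy in joules, (1/2) m v^2.
#' @export
kinetic_energy <- function(m_g, v) {
  if (any(m_g <= 0)) stop("mass must be positive")
  0.5 * m_g * v^2
}

#' Kinetic energy density (per jumping-muscle mass)
#'
#' @param KE kinetic energy, J.
#' @param muscle_mass jumping-muscle mass, kg.
#' @return J kg^-1.
#' @export
kinetic_energy_density <- function(KE, muscle_mass) {
  if (any(muscle_mass <= 0)) stop("muscle mass must be positive")
  KE / muscle_mass
}

#' Mean jump power and power density
#'
#' Power is kinetic energy delivered over the take-off interval; power
#' density expresses it per unit jumping-muscle mass.
#'
#' @param KE kinetic energy, J.
#' @param t time to take-off, s (> 0).
#' @param P power, W.
#' @param muscle_mass jumping-muscle mass, kg.
#' @return `jump_power`: W. `power_density`: W kg^-1.
#' @export
jump_power <- function(KE, t) {
  if (any(t <= 0)) stop("time to take-off must be positive")
  KE / t
}

#' @rdname jump_power
#' @export
power_density <- function(P, muscle_mass) {
  if (any(muscle_mass <= 0)) stop("muscle mass must be positive")
  P / muscle_mass
}

#' Effective leg-spring stiffness by conservation of energy
#'
#' The jumper is modelled as a linear spring released over the acceleration
#' distance x that delivers the observed take-off kinetic energy:
#' (1/2) k x^2 = (1/2) m v^2, hence k_g = m v^2 / x^2. Gravity is excluded
#' from the energy bookkeeping (1-2% of the budget at these scales).
#'
#' @param m_g jumper mass, kg.
#' @param v take-off speed, m s^-1.
#' @param x acceleration distance, m (> 0), from
#'   [acceleration_distance()].
#' @return Effective stiffness k_g in N m^-1.
#' @export
grasshopper_stiffness <- function(m_g, v, x) {
  if (any(x <= 0)) stop("acceleration distance must be positive")
  if (any(m_g <= 0)) stop("mass must be positive")
  m_g * v^2 / x^2
}

#' Take-off speed of the equivalent linear-spring launch
#'
#' Inverts the conservation-of-energy stiffness model: a spring of stiffness
#' k released over stroke x launches mass m at v = x sqrt(k / m).
#'
#' @param k_g effective stiffness, N m^-1.
#' @param m_g jumper mass, kg.
#' @param x acceleration distance (stroke), m.
#' @return Take-off speed, m s^-1.
#' @export
spring_launch_speed <- function(k_g, m_g, x) {
  if (any(m_g <= 0)) stop("mass must be positive")
  if (any(k_g < 0)) stop("stiffness must be non-negative")
  x * sqrt(k_g / m_g)
}

#' Derive the full per-jump variable record
#'
#' Runs the kinematic and energetic extraction for one calibrated recording:
#' take-off velocity and elevation, platform displacement and deformed-plane
#' angle, acceleration distance (leg geometry), mean acceleration, kinetic
#' energy and its density, power and its density, effective stiffness, and
#' the stiffness/mass ratios where the platform stiffness is known.
#'
#' @param recording a [jump_recording()].
#' @param morph the animal's [morphometrics()].
#' @param k_p platform stiffness at the jump position, N m^-1 (`NA` for
#'   control jumps from the rigid surface).
#' @param m_p platform (effective) mass, kg, for the mass ratio (`NA` if
#'   unknown).
#' @return One-row data frame of jump variables in SI units.
#' @export
jump_variables <- function(recording, morph, k_p = NA_real_, m_p = NA_real_) {
  stopifnot(inherits(recording, "jump_recording"),
            inherits(morph, "morphometrics"))
  pd <- platform_displacement(recording)
  v <- take_off_velocity(recording)
  t <- time_to_takeoff(recording)
  x <- acceleration_distance(morph)
  KE <- kinetic_energy(morph$body_mass, v)
  P <- if (t > 0) jump_power(KE, t) else NA_real_
  k_g <- grasshopper_stiffness(morph$body_mass, v, x)
  data.frame(
    animal_id = recording$animal_id,
    platform_id = recording$platform_id,
    line_index = recording$line_index,
    time_to_takeoff_s = t,
    velocity_m_s = v,
    elevation_deg = elevation(recording, pd$plane_angle_deg),
    platform_displacement_m = pd$displacement,
    platform_angle_deg = pd$plane_angle_deg,
    acceleration_distance_m = x,
    acceleration_m_s2 = if (t > 0) mean_acceleration(v, t) else NA_real_,
    kinetic_energy_J = KE,
    kinetic_energy_density_J_kg = kinetic_energy_density(KE, morph$muscle_mass),
    power_W = P,
    power_density_W_kg = if (is.na(P)) NA_real_ else
      power_density(P, morph$muscle_mass),
    k_g_N_m = k_g,
    k_p_N_m = k_p,
    stiffness_ratio = if (is.na(k_p)) NA_real_ else stiffness_ratio(k_g, k_p),
    mass_ratio = if (is.na(m_p)) NA_real_ else
      mass_ratio(morph$body_mass, m_p),
    stringsAsFactors = FALSE
  )
}

#' Per-animal effective stiffness from control jumps
#'
#' Each animal's k_g is the mean of the per-jump stiffness estimates over
#' that animal's control (rigid-surface) jumps; the population value used
#' for the regime split is the mean of those per-animal values.
#'
#' @param jump_table canonical jump table (rows for >= 1 animal).
#' @return Data frame `animal_id`, `k_g_N_m`; the across-animal mean is in
#'   attribute `mean_k_g`.
#' @export
animal_stiffness <- function(jump_table) {
  ctrl <- jump_table[jump_table$platform_id == "control", ]
  if (nrow(ctrl) == 0L) stop("no control jumps in table")
  per <- stats::aggregate(k_g_N_m ~ animal_id, data = ctrl, FUN = mean)
  attr(per, "mean_k_g") <- mean(per$k_g_N_m)
  per
}
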