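#' Trapezoidal motion segment
#'
#' A single point-to-point move with constant acceleration, an optional
#' constant-speed cruise, and constant deceleration to rest. When the
#' commanded distance is shorter than `vmax^2 / accel` the profile is
#' triangular: the peak speed `sqrt(accel * |distance|)` is reached at the
#' midpoint and `vmax` is never attained.
#'
#' @param start_time Segment start time (s).
#' @param distance Signed commanded displacement (mm).
#' @param accel Acceleration magnitude (mm/s^2), used for both the ramp-up
#'   and the ramp-down. Must be positive.
#' @param vmax Speed ceiling (mm/s). Must be positive.
#' @return An object of class `trap_segment`.
#' @examples
#' seg <- trap_segment(0, 20, accel = 3, vmax = 4)
#' trapezoid_displacement(segment_duration(seg), seg) # 20 mm
#' @export
trap_segment <- function(start_time, distance, accel, vmax) {
  stopifnot(is.numeric(start_time), length(start_time) == 1L,
            is.numeric(distance), length(distance) == 1L)
  if (!is.numeric(accel) || length(accel) != 1L || !is.finite(accel) || accel <= 0)
    stop("`accel` must be a positive finite number (mm/s^2)")
  if (!is.numeric(vmax) || length(vmax) != 1L || !is.finite(vmax) || vmax <= 0)
    stop("`vmax` must be a positive finite number (mm/s)")
  structure(list(start_time = start_time, distance = distance,
                 accel = accel, vmax = vmax),
            class = "trap_segment")
}

#' Peak speed actually reached by a trapezoid segment
#' @param seg A [trap_segment()].
#' @return Peak speed in mm/s: `min(vmax, sqrt(accel * |distance|))`.
#' @export
segment_peak_speed <- function(seg) {
  min(seg$vmax, sqrt(seg$accel * abs(seg$distance)))
}

#' Duration of a trapezoid segment
#' @param seg A [trap_segment()].
#' @return Move duration in seconds (0 for zero distance).
#' @export
segment_duration <- function(seg) {
  d <- abs(seg$distance)
  if (d == 0) return(0)
  vpk <- segment_peak_speed(seg)
  ramp <- vpk / seg$accel
  cruise <- (d - vpk^2 / seg$accel) / vpk
  2 * ramp + cruise
}

#' Displacement along a trapezoid segment at time t
#'
#' Integrates the piecewise-constant acceleration profile in closed form.
#' Before `start_time` the displacement is 0; after the segment ends it
#' stays at `distance`.
#'
#' @param t Time(s) in seconds; vectorised.
#' @param seg A [trap_segment()].
#' @return Signed displacement (mm) at each `t`.
#' @export
trapezoid_displacement <- function(t, seg) {
  stopifnot(inherits(seg, "trap_segment"))
  d <- abs(seg$distance)
  if (d == 0) return(rep(0, length(t)))
  sgn <- sign(seg$distance)
  a <- seg$accel
  vpk <- segment_peak_speed(seg)
  ramp <- vpk / a
  cruise <- (d - vpk^2 / a) / vpk
  dur <- 2 * ramp + cruise
  tr <- t - seg$start_time
  disp <- ifelse(tr <= 0, 0,
          ifelse(tr < ramp, 0.5 * a * tr^2,
          ifelse(tr < ramp + cruise, 0.5 * a * ramp^2 + vpk * (tr - ramp),
          ifelse(tr < dur, d - 0.5 * a * (dur - tr)^2, d))))
  sgn * disp
}

#' Velocity along a trapezoid segment at time t
#' @inheritParams trapezoid_displacement
#' @return Signed velocity (mm/s) at each `t`.
#' @export
trapezoid_velocity <- function(t, seg) {
  stopifnot(inherits(seg, "trap_segment"))
  d <- abs(seg$distance)
  if (d == 0) return(rep(0, length(t)))
  sgn <- sign(seg$distance)
  a <- seg$accel
  vpk <- segment_peak_speed(seg)
  ramp <- vpk / a
  cruise <- (d - vpk^2 / a) / vpk
  dur <- 2 * ramp + cruise
  tr <- t - seg$start_time
  v <- ifelse(tr <= 0, 0,
       ifelse(tr < ramp, a * tr,
       ifelse(tr < ramp + cruise, vpk,
       ifelse(tr < dur, a * (dur - tr), 0))))
  sgn * v
}

#' Minimum commanded move that just attains the speed ceiling
#'
#' For a trapezoidal profile the shortest accelerate-then-decelerate move
#' whose peak speed equals `vmax` has no cruise phase and covers
#' `vmax^2 / accel` (two symmetric ramps of `vmax^2 / (2 accel)` each).
#'
#' @param vmax Speed ceiling (mm/s), positive.
#' @param accel Acceleration magnitude (mm/s^2), positive.
#' @return Distance in mm.
#' @examples
#' min_distance_to_reach_vmax(50, 250) # 10 mm
#' @export
min_distance_to_reach_vmax <- function(vmax, accel) {
  if (!is.numeric(vmax) || any(vmax <= 0)) stop("`vmax` must be positive")
  if (!is.numeric(accel) || any(accel <= 0)) stop("`accel` must be positive")
  vmax^2 / accel
}

#' Combined speed limit of stacked translation stages
#'
#' Stages mounted in series and driven simultaneously add their velocities,
#' so the achievable speed along the common axis is the sum of the
#' per-stage maxima.
#'
#' @param per_stage Per-stage maximum speed (mm/s). Default 2.6.
#' @param n_stages Number of stacked stages. Default 2.
#' @return Combined maximum speed (mm/s).
#' @examples
#' combined_stage_speed_limit() # 5.2
#' @export
combined_stage_speed_limit <- function(per_stage = 2.6, n_stages = 2) {
  stopifnot(per_stage > 0, n_stages >= 1)
  n_stages * per_stage
}

#' Motion profile: an ordered sequence of trapezoid segments along one axis
#'
#' @param segments List of [trap_segment()] objects, sorted by start time and
#'   non-overlapping (each segment finishes before the next starts).
#' @param axis_direction Unit 3-vector in the probe frame
#'   (x = lateral, y = elevational, z = depth) along which the displacement
#'   acts. Normalised internally.
#' @return An object of class `motion_profile`.
#' @export
motion_profile <- function(segments,
                           axis_direction = c(1, 0, 0)) {
  stopifnot(is.list(segments), all(vapply(segments, inherits, TRUE, "trap_segment")))
  if (length(segments) > 1) {
    starts <- vapply(segments, `[[`, 0, "start_time")
    ends <- starts + vapply(segments, segment_duration, 0)
    if (is.unsorted(starts, strictly = FALSE))
      stop("segments must be sorted by start time")
    if (any(starts[-1] < ends[-length(ends)] - 1e-12))
      stop("segments must not overlap in time")
  }
  stopifnot(length(axis_direction) == 3, sum(axis_direction^2) > 0)
  structure(list(segments = segments,
                 axis_direction = axis_direction / sqrt(sum(axis_direction^2))),
            class = "motion_profile")
}

#' Scalar displacement of a motion profile at time t
#' @param profile A [motion_profile()].
#' @param t Time(s) in seconds; vectorised.
#' @return Signed displacement (mm) along the profile axis.
#' @export
profile_displacement <- function(profile, t) {
  stopifnot(inherits(profile, "motion_profile"))
  disp <- rep(0, length(t))
  for (seg in profile$segments) disp <- disp + trapezoid_displacement(t, seg)
  disp
}

#' 3-vector displacement of a motion profile at time t
#' @inheritParams profile_displacement
#' @return `length(t)` x 3 matrix of probe-frame displacements (mm).
#' @export
profile_displacement3 <- function(profile, t) {
  outer(profile_displacement(profile, t), profile$axis_direction)
}

#' Total duration of a motion profile
#' @param profile A [motion_profile()].
#' @return End time (s) of the last segment.
#' @export
profile_duration <- function(profile) {
  if (length(profile$segments) == 0) return(0)
  max(vapply(profile$segments, function(s) s$start_time + segment_duration(s), 0))
}

#' Build a stage motion protocol
#'
#' Two protocols mirror the experimental stage programmes: `"mixed"`
#' alternates 4 mm/s and 2 mm/s legs over the full range within each round
#' trip (the demonstration profile), and `"single_speed"` runs every leg at
#' one speed (the speed-sweep profile). Legs span `range` mm out and back
#' with a dwell between legs; acceleration and deceleration are fixed at
#' `accel`.
#'
#' @param kind `"mixed"` or `"single_speed"`.
#' @param speed Leg speed (mm/s) for `single_speed`; ignored for `mixed`.
#'   Must not exceed the combined stage limit
#'   ([combined_stage_speed_limit()], 5.2 mm/s by default).
#' @param range Leg excursion (mm). Default 20.
#' @param n_round_trips Number of out-and-back round trips. Default 5.
#' @param dwell Rest time between legs (s). Default 1.
#' @param accel Stage acceleration (mm/s^2). Default 3.
#' @param axis_direction Probe-frame direction of motion; see
#'   [motion_profile()]. `c(1, 0, 0)` is lateral, `c(0, 1, 0)` elevational,
#'   and `c(1, 1, 0)/sqrt(2)` the default "arbitrary" diagonal.
#' @param start_time Time of the first leg's start (s). Default 0.
#' @return A [motion_profile()].
#' @export
build_protocol <- function(kind = c("single_speed", "mixed"), speed = 5,
                           range = 20, n_round_trips = 5, dwell = 1,
                           accel = 3, axis_direction = c(1, 0, 0),
                           start_time = 0) {
  kind <- match.arg(kind)
  stopifnot(range > 0, n_round_trips >= 1)
  limit <- combined_stage_speed_limit()
  if (kind == "single_speed" && speed > limit + 1e-12)
    stop(sprintf("speed %.3g mm/s exceeds the combined stage maximum of %.3g mm/s",
                 speed, limit))
  if (kind == "single_speed" && speed <= 0) stop("`speed` must be positive")
  leg_speeds <- switch(kind,
    single_speed = rep(speed, 2L * n_round_trips),
    mixed = rep(c(4, 2), n_round_trips))
  segs <- vector("list", length(leg_speeds))
  t0 <- start_time
  dir <- 1
  for (i in seq_along(leg_speeds)) {
    segs[[i]] <- trap_segment(t0, dir * range, accel, leg_speeds[i])
    t0 <- t0 + segment_duration(segs[[i]]) + dwell
    dir <- -dir
  }
  motion_profile(segs, axis_direction)
}
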