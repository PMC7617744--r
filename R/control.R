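#' Processing-loop stage latencies
#'
#' Per-cycle durations of the three processing stages. Beamforming is a
#' fixed cost; registration time is drawn uniformly from its range each
#' cycle (convergence-dependent in the real system); the robot stage is a
#' fixed command-transmission cost plus the trapezoidal execution time of
#' the commanded move, which together span roughly 0.03-0.25 s for the move
#' lengths arising in tracking. An optional extra uniformly drawn command
#' latency is available for sensitivity studies.
#'
#' @param beamform_latency Seconds. Default 0.04.
#' @param registration_latency `c(min, max)` seconds. Default
#'   `c(0.04, 0.3)`.
#' @param command_latency Fixed command transmission cost (s). Default 0.03.
#' @param extra_command_latency `c(min, max)` seconds drawn per cycle on top
#'   of the fixed cost. Default `c(0, 0)`.
#' @return An object of class `loop_timings`.
#' @export
loop_timings <- function(beamform_latency = 0.04,
                         registration_latency = c(0.04, 0.3),
                         command_latency = 0.03,
                         extra_command_latency = c(0, 0)) {
  stopifnot(beamform_latency >= 0, command_latency >= 0,
            length(registration_latency) == 2,
            registration_latency[1] >= 0,
            registration_latency[1] <= registration_latency[2],
            length(extra_command_latency) == 2,
            extra_command_latency[1] >= 0,
            extra_command_latency[1] <= extra_command_latency[2])
  structure(list(beamform_latency = beamform_latency,
                 registration_latency = registration_latency,
                 command_latency = command_latency,
                 extra_command_latency = extra_command_latency),
            class = "loop_timings")
}

#' Robot kinematic state
#'
#' @param pose Probe-frame offset from the start pose (mm 3-vector).
#' @param accel Acceleration/deceleration magnitude (mm/s^2). Default 250.
#' @param vmax Maximum speed (mm/s). Default 50.
#' @param busy_until Time at which the current move completes (s).
#' @return An object of class `robot_state`.
#' @export
robot_state <- function(pose = c(0, 0, 0), accel = 250, vmax = 50,
                        busy_until = 0) {
  stopifnot(accel > 0, vmax > 0)
  structure(list(pose = as.numeric(pose), accel = accel, vmax = vmax,
                 busy_until = busy_until, moves = list()),
            class = "robot_state")
}

#' Execute a straight-line trapezoidal robot move
#'
#' The probe travels from its current pose to `target_pose` along a straight
#' line with a trapezoidal speed profile; moves shorter than
#' `vmax^2 / accel` (about 10 mm at the defaults) never cruise, so the probe
#' only accelerates and decelerates.
#'
#' @param state A [robot_state()]; must not be busy at `t_start`.
#' @param target_pose Destination (mm 3-vector).
#' @param t_start Move start time (s).
#' @return The updated `robot_state`; query the pose over time with
#'   [robot_pose_at()].
#' @export
robot_move <- function(state, target_pose, t_start) {
  stopifnot(inherits(state, "robot_state"))
  if (t_start < state$busy_until - 1e-12)
    stop("robot is busy until ", state$busy_until, " s; command dropped")
  delta <- as.numeric(target_pose) - state$pose
  dist <- sqrt(sum(delta^2))
  if (dist == 0) {
    state$busy_until <- t_start
    return(state)
  }
  seg <- trap_segment(t_start, dist, state$accel, state$vmax)
  dir <- delta / dist
  state$moves[[length(state$moves) + 1L]] <-
    list(seg = seg, dir = dir, from = state$pose)
  state$pose <- state$pose + delta
  state$busy_until <- t_start + segment_duration(seg)
  state
}

#' Robot pose trajectory
#' @param state A [robot_state()].
#' @param t Times (s), vectorised.
#' @return `length(t)` x 3 matrix of poses (mm).
#' @export
robot_pose_at <- function(state, t) {
  pose <- matrix(0, length(t), 3)
  for (m in state$moves) {
    d <- trapezoid_displacement(t, m$seg)
    pose <- pose + outer(d, m$dir)
  }
  pose
}

move_duration <- function(dist, accel, vmax) {
  if (dist <= 0) return(0)
  segment_duration(trap_segment(0, dist, accel, vmax))
}

#' Safety workspace for robot commands
#'
#' An axis-aligned box of admissible probe offsets. Commands whose target
#' pose falls outside the box are withheld (closed-interval boundaries).
#'
#' @param lateral,elevational,depth `c(min, max)` limits in mm. Defaults
#'   `c(-50, 50)`, `c(-50, 50)`, `c(-5, 5)`.
#' @param center Box centre (mm 3-vector).
#' @return An object of class `safety_workspace`.
#' @export
safety_workspace <- function(lateral = c(-50, 50), elevational = c(-50, 50),
                             depth = c(-5, 5), center = c(0, 0, 0)) {
  stopifnot(lateral[1] <= lateral[2], elevational[1] <= elevational[2],
            depth[1] <= depth[2])
  structure(list(lateral = lateral, elevational = elevational, depth = depth,
                 center = as.numeric(center)),
            class = "safety_workspace")
}

#' Clamp a robot command against the safety workspace
#'
#' @param workspace A [safety_workspace()].
#' @param target_pose Commanded pose (mm 3-vector).
#' @return List with `pose` (unchanged) and `withheld` (TRUE when the pose
#'   lies outside the workspace and the command must not be sent).
#' @export
clamp_command <- function(workspace, target_pose) {
  p <- as.numeric(target_pose) - workspace$center
  inside <- p[1] >= workspace$lateral[1] && p[1] <= workspace$lateral[2] &&
    p[2] >= workspace$elevational[1] && p[2] <= workspace$elevational[2] &&
    p[3] >= workspace$depth[1] && p[3] <= workspace$depth[2]
  list(pose = as.numeric(target_pose), withheld = !inside)
}

#' Asynchronous closed-loop target-tracking simulation
#'
#' Event-driven simulation of the acquisition/processing/robot timeline.
#' Acquisition emits frames at a strictly uniform rate regardless of
#' processing. Each processing cycle (i) beamforms the latest available
#' frame on the cropped low-resolution online grid, (ii) estimates the
#' target's translation relative to the first frame, and (iii) commands the
#' robot to an absolute pose that cancels it (withheld if outside the
#' safety workspace), then repeats. The next cycle waits for the robot to
#' finish executing before grabbing its frame (the loop is sequential).
#'
#' The landmark's residual displacement relative to the first frame (probe
#' frame, lateral and elevational) is logged for every acquired frame.
#'
#' @param scene A [phantom_scene()].
#' @param profile Stage [motion_profile()].
#' @param timings A [loop_timings()].
#' @param workspace A [safety_workspace()].
#' @param duration Simulated time (s). Default: profile duration + 2 s.
#' @param volume_rate Acquisition rate (Hz). Default 85.
#' @param probe A [probe_model()].
#' @param psf A [psf_model()]; default [default_psf()].
#' @param online_pitch Online beamforming pitch (mm). Default 0.4 (two
#'   wavelengths).
#' @param crop_size Online crop edge length (mm). Default 12.5.
#' @param crop_center Crop centre in the probe frame; defaults to the
#'   landmark's initial position.
#' @param detection `"image"` runs the translation-only registration on
#'   rendered online volumes; `"ideal"` uses the geometric displacement plus
#'   `detection_noise_sd` mm of Gaussian noise per axis.
#' @param detection_noise_sd Noise for `"ideal"` detection (mm).
#'   Default 0.02.
#' @param servo_axes Axes the servo corrects; depth commands are zeroed by
#'   default (axial probe motion must not chase the target).
#' @param noise_sigma Rendering noise for the online volumes. Default 0.02.
#' @param tracking Enable the servo; `FALSE` leaves the probe fixed.
#' @param robot_accel,robot_vmax Robot kinematics (mm/s^2, mm/s). Defaults
#'   250 and 50.
#' @param seed RNG seed for latency draws and rendering noise.
#' @return An object of class `tracking_log`: list with `frames` (per-frame
#'   time, residual components and magnitude, landmark-in-FoV flag),
#'   `cycles` (per-cycle record), and the final `robot` state.
#' @export
run_async_loop <- function(scene, profile, timings = loop_timings(),
                           workspace = safety_workspace(),
                           duration = NULL, volume_rate = 85,
                           probe = probe_model(), psf = default_psf(probe),
                           online_pitch = 0.4, crop_size = 12.5,
                           crop_center = NULL,
                           detection = c("image", "ideal"),
                           detection_noise_sd = 0.02,
                           servo_axes = c(TRUE, TRUE, FALSE),
                           noise_sigma = 0.02, tracking = TRUE,
                           robot_accel = 250, robot_vmax = 50,
                           seed = 1L) {
  detection <- match.arg(detection)
  stopifnot(inherits(scene, "phantom_scene"), inherits(profile, "motion_profile"))
  if (is.null(duration)) duration <- profile_duration(profile) + 2
  set.seed(seed)
  if (is.null(crop_center)) crop_center <- scene$landmark_center
  grid <- centered_grid(crop_center, crop_size, online_pitch)
  robot <- robot_state(accel = robot_accel, vmax = robot_vmax)
  frame_times <- seq(0, duration, by = 1 / volume_rate)
  frame_times <- frame_times[seq_len(floor(duration * volume_rate))]

  landmark0 <- scene_landmark(scene)
  target_disp <- function(t) profile_displacement(profile, t) * profile$axis_direction

  ref_vol <- NULL
  if (detection == "image" && tracking) {
    sc0 <- scene_at_time(scene, profile, 0)
    ref_vol <- render_bmode(sc0, probe, grid, psf, noise_sigma)
  }

  cyc <- list()
  tcur <- timings$beamform_latency  # first usable frame processed after t=0
  prev_det <- c(0, 0, 0)
  while (tracking && tcur < duration) {
    tf_idx <- findInterval(tcur, frame_times)
    if (tf_idx < 1) { tcur <- frame_times[1] + 1e-6; next }
    tf <- frame_times[tf_idx]
    reg_lat <- stats::runif(1, timings$registration_latency[1],
                            timings$registration_latency[2])
    extra <- if (timings$extra_command_latency[2] > 0)
      stats::runif(1, timings$extra_command_latency[1],
                   timings$extra_command_latency[2]) else 0
    # --- measurement at the frame time
    probe_pose_tf <- robot_pose_at(robot, tf)[1, ]
    true_resid <- target_disp(tf) - probe_pose_tf
    det_ok <- TRUE
    if (detection == "image") {
      pr <- probe; pr$position <- probe_pose_tf
      sc <- scene_at_time(scene, profile, tf)
      mov <- render_bmode(sc, pr, grid, psf, noise_sigma)
      reg <- estimate_translation(ref_vol, mov, n_pyramid_levels = 3,
                                  init = prev_det)
      det <- reg$transform$translation
      det_ok <- reg$converged && all(is.finite(det))
      if (!det_ok) det <- c(0, 0, 0)
    } else {
      det <- true_resid + stats::rnorm(3, 0, detection_noise_sd)
    }
    det[!servo_axes] <- 0
    prev_det <- det * c(servo_axes)
    t_issue <- tcur + timings$beamform_latency + reg_lat +
      timings$command_latency + extra
    t_issue <- max(t_issue, robot$busy_until)
    target_pose <- probe_pose_tf + det
    cl <- clamp_command(workspace, target_pose)
    issued <- det_ok && !cl$withheld && sqrt(sum(det^2)) > 1e-6
    if (issued) robot <- robot_move(robot, target_pose, t_issue)
    cyc[[length(cyc) + 1L]] <- data.frame(
      t_cycle_start = tcur, t_frame = tf,
      det_dx_mm = det[1], det_dy_mm = det[2], det_dz_mm = det[3],
      cmd_issued = issued, withheld = cl$withheld,
      t_issue = t_issue, t_arrive = robot$busy_until)
    # a cycle can never outpace the acquisition of a new frame
    tcur <- max(robot$busy_until, t_issue,
                tf + 1 / volume_rate + 1e-9)
  }

  # per-frame residual log (geometric landmark displacement in the FoV)
  probe_traj <- robot_pose_at(robot, frame_times)
  disp <- t(vapply(frame_times, target_disp, numeric(3)))
  resid <- disp - probe_traj
  resid <- sweep(resid, 2, resid[1, ], "-")
  frames <- data.frame(
    t_s = frame_times,
    residual_x_mm = resid[, 1], residual_y_mm = resid[, 2],
    residual_z_mm = resid[, 3],
    residual_mm = sqrt(resid[, 1]^2 + resid[, 2]^2),
    robot_x_mm = probe_traj[, 1], robot_y_mm = probe_traj[, 2],
    robot_z_mm = probe_traj[, 3])
  # landmark probe-frame position per frame, for field-of-view audit
  lm_probe <- matrix(landmark0, length(frame_times), 3, byrow = TRUE) +
    disp - probe_traj
  frames$landmark_in_fov <- abs(lm_probe[, 1]) <= 7.5 & abs(lm_probe[, 2]) <= 7.5

  cycles <- if (length(cyc)) do.call(rbind, cyc) else
    data.frame(t_cycle_start = numeric(0))
  structure(list(frames = frames, cycles = cycles, robot = robot,
                 grid = grid, volume_rate = volume_rate,
                 scene = scene, profile = profile, probe = probe, psf = psf,
                 seed = seed),
            class = "tracking_log")
}

#' Write a tracking log as CSV
#' @param log A `tracking_log` from [run_async_loop()].
#' @param path Output CSV path.
#' @return The frame table, invisibly.
#' @export
write_tracking_log <- function(log, path) {
  utils::write.csv(log$frames, path, row.names = FALSE)
  invisible(log$frames)
}
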