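#' Default run configuration
#'
#' A fully serialisable description of a desk-scale run: scene, probe and
#' grid parameters, motion protocol, loop timings, safety workspace, ULM
#' parameters, seeds and output geometry. Every field can be overridden
#' via `...`; unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # scene
    n_speckle = 2000, n_bubbles = 20, mean_flow_speed = 1,
    channel_radius = 0.1, crossing_angle_deg = 30, channel_depth = 20,
    # protocol
    protocol = "single_speed", speed = 5, range = 20, n_round_trips = 1,
    dwell = 1, stage_accel = 3, direction = "lateral",
    # probe / grids
    center_frequency = 7.8, sound_speed = 1540, volume_rate = 85,
    duration = NA_real_, online_pitch = 0.4, crop_size = 12.5,
    offline_pitch = 0.1, fov_half = 7.5,
    # loop
    beamform_latency = 0.04, registration_latency = c(0.04, 0.3),
    command_latency = 0.03, detection = "image", tracking = TRUE,
    noise_sigma = 0.02,
    # ULM
    ncc_threshold = 0.5, upsample = 5, persistence = 4, max_link_speed = 10,
    map_pitch = 0.02,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration (YAML)
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return The config (reader) or `path` invisibly (writer).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Hash of a configuration
#'
#' Short deterministic digest used to stamp run artefacts so that outputs
#' from different configurations cannot be silently mixed.
#'
#' @param config A `run_config`.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

direction_vector <- function(direction) {
  switch(direction,
         lateral = c(1, 0, 0),
         elevational = c(0, 1, 0),
         arbitrary = c(1, 1, 0) / sqrt(2),
         stop("unknown direction: ", direction))
}

config_scene <- function(cfg) {
  phantom_scene(n_speckle = cfg$n_speckle, n_bubbles = cfg$n_bubbles,
                mean_flow_speed = cfg$mean_flow_speed,
                channel_radius = cfg$channel_radius,
                crossing_angle_deg = cfg$crossing_angle_deg,
                channel_depth = cfg$channel_depth, seed = cfg$seed)
}

config_profile <- function(cfg) {
  build_protocol(kind = cfg$protocol, speed = cfg$speed, range = cfg$range,
                 n_round_trips = cfg$n_round_trips, dwell = cfg$dwell,
                 accel = cfg$stage_accel,
                 axis_direction = direction_vector(cfg$direction))
}

write_manifest <- function(cfg, out_dir, files) {
  jsonlite::write_json(list(config_hash = config_hash(cfg), files = files),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

check_manifest <- function(cfg, dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(mf)
  if (!identical(m$config_hash, config_hash(cfg)))
    stop("artefacts in ", dir, " were produced under a different configuration")
  invisible(TRUE)
}

#' Simulate an acquisition and write its artefacts
#'
#' Renders B-mode and contrast frame sequences for the configured scene and
#' protocol (static probe), and writes ground-truth tables: the scatterer
#' snapshot, per-frame landmark trajectory and bubble positions.
#'
#' @param config A `run_config` from [default_config()].
#' @param out_dir Output directory (created). Default from the config.
#' @param n_frames Frame-count override for desk-scale runs.
#' @return Invisibly, a list of written file paths.
#' @export
cmd_simulate <- function(config = default_config(), out_dir = config$out_dir,
                         n_frames = NULL) {
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  scene <- config_scene(config)
  profile <- config_profile(config)
  probe <- probe_model(center_frequency = config$center_frequency,
                       sound_speed = config$sound_speed)
  psf <- default_psf(probe)
  dur <- if (is.na(config$duration)) profile_duration(profile) + 1 else
    config$duration
  n <- floor(dur * config$volume_rate)
  if (!is.null(n_frames)) n <- min(n, n_frames)
  grid <- centered_grid(scene$landmark_center, config$crop_size,
                        config$online_pitch)
  files <- character(0)
  truth_landmark <- data.frame(frame = integer(0))
  truth_bubbles <- list()
  for (k in seq_len(n)) {
    t <- (k - 1) / config$volume_rate
    sc <- scene_at_time(scene, profile, t)
    bm <- render_bmode(sc, probe, grid, psf, config$noise_sigma,
                       fov_half = rep(config$fov_half, 2))
    ce <- render_contrast(sc, probe, grid, psf, config$noise_sigma / 4,
                          fov_half = rep(config$fov_half, 2))
    fb <- file.path(out_dir, sprintf("bmode_%04d.nii.gz", k))
    fc <- file.path(out_dir, sprintf("contrast_%04d.nii.gz", k))
    write_volume_nifti(bm, fb)
    write_volume_nifti(ce, fc)
    files <- c(files, fb, fc)
    lm <- scene_landmark(sc)
    truth_landmark <- rbind(truth_landmark,
                            data.frame(frame = k, t_s = t, x_mm = lm[1],
                                       y_mm = lm[2], z_mm = lm[3]))
    bp <- bubble_positions(sc)
    if (nrow(bp))
      truth_bubbles[[k]] <- data.frame(frame = k, t_s = t,
                                       x_mm = bp[, 1] + sc$displacement[1],
                                       y_mm = bp[, 2] + sc$displacement[2],
                                       z_mm = bp[, 3] + sc$displacement[3])
  }
  f1 <- file.path(out_dir, "landmark_truth.csv")
  utils::write.csv(truth_landmark, f1, row.names = FALSE)
  f2 <- file.path(out_dir, "bubble_truth.csv")
  utils::write.csv(do.call(rbind, truth_bubbles), f2, row.names = FALSE)
  f3 <- file.path(out_dir, "scatterers.csv")
  utils::write.csv(scene_scatterers(scene), f3, row.names = FALSE)
  files <- c(files, f1, f2, f3)
  write_manifest(config, out_dir, basename(files))
  invisible(list(files = files, out_dir = out_dir))
}

#' Run the closed-loop tracking simulation and write its log
#'
#' @param config A `run_config`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return The `tracking_log` (invisibly when writing).
#' @export
cmd_track <- function(config = default_config(), out_dir = config$out_dir) {
  scene <- config_scene(config)
  profile <- config_profile(config)
  probe <- probe_model(center_frequency = config$center_frequency,
                       sound_speed = config$sound_speed)
  timings <- loop_timings(beamform_latency = config$beamform_latency,
                          registration_latency = config$registration_latency,
                          command_latency = config$command_latency)
  dur <- if (is.na(config$duration)) NULL else config$duration
  log <- run_async_loop(scene, profile, timings,
                        duration = dur, volume_rate = config$volume_rate,
                        probe = probe, online_pitch = config$online_pitch,
                        crop_size = config$crop_size,
                        detection = config$detection,
                        noise_sigma = config$noise_sigma,
                        tracking = config$tracking, seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "tracking_log.csv")
    write_tracking_log(log, f1)
    ser <- detect_onset(series_from_log(log))
    stats <- tryCatch(residual_stats(ser), error = function(e) NULL)
    summ <- list(mean_residual_mm = if (is.null(stats)) NA else stats$mean_mm,
                 sd_residual_mm = if (is.null(stats)) NA else stats$sd_mm,
                 in_fov_fraction = mean(log$frames$landmark_in_fov))
    jsonlite::write_json(summ, file.path(out_dir, "residual_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(config, out_dir,
                   c("tracking_log.csv", "residual_summary.json"))
    return(invisible(log))
  }
  log
}

#' Offline reconstruction: motion correction, ULM maps and FSC
#'
#' Runs the post-processing chain on a simulated tracked acquisition:
#' per-frame 6-DoF rigid registration (warm-started), Lagrangian-corrected
#' contrast frames, bubble localisation and tracking, super-resolution
#' density/speed maps (with and without motion correction for comparison),
#' smoothing, and odd/even-split Fourier shell correlation.
#'
#' @param config A `run_config`.
#' @param log Optional `tracking_log` from [cmd_track()] (re-run when
#'   omitted).
#' @param n_frames Number of frames to reconstruct. Default 120.
#' @param frame_stride Use every k-th acquired frame. Default 4.
#' @param recon_size Edge of the reconstruction volume (mm). Default 6.
#' @param map_depth Depth extent of the super-resolution map slab (mm).
#'   Default 1.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param use_true_transforms Skip registration and use ground-truth motion
#'   (for calibration studies). Default FALSE.
#' @return List with `tracks`, `maps`, `maps_uncorrected`, `maps_smooth`,
#'   `fsc`, `transforms`, `localisations`.
#' @export
cmd_reconstruct <- function(config = default_config(), log = NULL,
                            n_frames = 120, frame_stride = 4,
                            recon_size = 6, map_depth = 1,
                            out_dir = config$out_dir,
                            use_true_transforms = FALSE) {
  if (is.null(log)) log <- cmd_track(config, out_dir = NULL)
  scene <- log$scene
  profile <- log$profile
  probe <- log$probe
  psf <- log$psf
  rate_eff <- log$volume_rate / frame_stride
  idx <- seq(1, nrow(log$frames), by = frame_stride)
  idx <- idx[seq_len(min(n_frames, length(idx)))]
  ctr <- c(0, 0, scene$channels[[1]]$p0[3])
  grid_fine <- centered_grid(ctr, recon_size, config$offline_pitch)
  # reference frame
  ref_b <- NULL
  transforms <- vector("list", length(idx))
  frames_c <- vector("list", length(idx))
  locs <- vector("list", length(idx))
  prev <- NULL
  set.seed(config$seed + 7L)
  for (k in seq_along(idx)) {
    t <- log$frames$t_s[idx[k]]
    pr <- probe
    pr$position <- c(log$frames$robot_x_mm[idx[k]],
                     log$frames$robot_y_mm[idx[k]],
                     log$frames$robot_z_mm[idx[k]])
    sc <- scene_at_time(scene, profile, t)
    bm <- render_bmode(sc, pr, grid_fine, psf, config$noise_sigma)
    ce <- render_contrast(sc, pr, grid_fine, psf, config$noise_sigma / 4)
    if (k == 1) {
      ref_b <- bm
      transforms[[k]] <- rigid_transform(center = ctr)
    } else if (use_true_transforms) {
      disp <- profile_displacement(profile, t) * profile$axis_direction -
        pr$position
      disp0 <- -c(log$frames$robot_x_mm[idx[1]], log$frames$robot_y_mm[idx[1]],
                  log$frames$robot_z_mm[idx[1]])
      transforms[[k]] <- rigid_transform(disp - disp0, center = ctr)
    } else {
      init <- if (is.null(prev)) rigid_transform(center = ctr) else prev
      # the warm start keeps the remaining motion well inside the LM basin,
      # so the pyramid is only needed for the first registered frame
      rr <- estimate_rigid_lm(ref_b, bm, init = init, max_iter = 40,
                              n_pyramid_levels = if (k == 2) 3 else 1)
      transforms[[k]] <- rr$transform
      prev <- rr$transform
    }
    frames_c[[k]] <- ce
  }
  # localisation on motion-corrected contrast frames
  template <- reference_bubble_template(psf, config$offline_pitch)
  for (k in seq_along(idx)) {
    corr <- resample_volume(frames_c[[k]], transforms[[k]], grid = grid_fine)
    supp <- suppress_background(corr, noise_floor = 6 * config$noise_sigma / 4)
    sc_map <- ncc_map(supp, template)
    locs[[k]] <- localise(sc_map, supp, threshold = config$ncc_threshold,
                          upsample = config$upsample, frame = k)
  }
  all_locs <- do.call(rbind, locs)
  tracks <- link_tracks(all_locs, rate_eff, max_speed = config$max_link_speed)
  tracks <- persistence_filter(tracks, config$persistence)
  # the channels live in a thin slab at constant depth: restrict the fine
  # super-resolution grid to that slab instead of a full cube
  map_grid <- centered_grid(ctr, c(recon_size, recon_size, map_depth),
                            config$map_pitch)
  maps <- accumulate_maps(tracks, map_grid)
  # uncorrected control: same chain with identity transforms
  locs_u <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    supp <- suppress_background(frames_c[[k]],
                                noise_floor = 6 * config$noise_sigma / 4)
    sc_map <- ncc_map(supp, template)
    locs_u[[k]] <- localise(sc_map, supp, threshold = config$ncc_threshold,
                            upsample = config$upsample, frame = k)
  }
  tracks_u <- persistence_filter(
    link_tracks(do.call(rbind, locs_u), rate_eff,
                max_speed = max(config$max_link_speed, 2 * config$speed + 2)),
    config$persistence)
  maps_u <- accumulate_maps(tracks_u, map_grid)
  maps_smooth <- smooth_maps(maps)
  fsc <- NULL
  if (length(unique(tracks$track_id)) >= 2) {
    halves <- split_odd_even(tracks, map_grid)
    curve <- fsc_curve(halves$odd$density, halves$even$density)
    fsc <- list(curve = curve, resolution = fsc_resolution(curve))
  }
  out <- list(tracks = tracks, tracks_uncorrected = tracks_u, maps = maps,
              maps_uncorrected = maps_u, maps_smooth = maps_smooth,
              fsc = fsc, transforms = transforms, localisations = all_locs,
              grid = map_grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(all_locs, file.path(out_dir, "localisations.csv"),
                     row.names = FALSE)
    utils::write.csv(tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    write_transforms_csv(transforms, file.path(out_dir, "transforms.csv"))
    write_volume_nifti(maps$density, file.path(out_dir, "density.nii.gz"))
    write_volume_nifti(maps$speed, file.path(out_dir, "speed.nii.gz"))
    write_volume_nifti(maps_u$density,
                       file.path(out_dir, "density_uncorrected.nii.gz"))
    if (!is.null(fsc)) {
      write_fsc_csv(fsc$curve, file.path(out_dir, "fsc_curve.csv"))
      jsonlite::write_json(fsc$resolution,
                           file.path(out_dir, "fsc_resolution.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    write_manifest(config, out_dir,
                   c("localisations.csv", "tracks.csv", "transforms.csv"))
  }
  out
}

# synthetic single-bubble template rendered from the PSF model itself
reference_bubble_template <- function(psf, pitch, half_extent_fwhm = 1.6) {
  ext <- max(psf$fwhm) * half_extent_fwhm
  n <- 2L * ceiling(ext / pitch) + 1L
  g <- centered_grid(c(0, 0, 0), n * pitch, pitch)
  v <- render_points(rbind(c(0, 0, 0)), 1, g, psf, 0,
                     fov_half = c(1e6, 1e6))
  v$data <- v$data / max(v$data)
  class(v) <- c("psf_template", class(v))
  v
}
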