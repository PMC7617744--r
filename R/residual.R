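#' Intensity-weighted centroid of a region of interest
#'
#' Localises a bright scatterer by weighted centroiding: the ROI's minimum
#' intensity is subtracted as a background floor (configurable), and the
#' intensity-weighted mean position of the remaining mass is returned.
#'
#' @param volume An [ulm_volume()].
#' @param roi Optional ROI as `list(center =, size =)` in mm; default whole
#'   volume.
#' @param subtract_floor Subtract the ROI minimum before weighting.
#'   Default TRUE.
#' @return mm 3-vector.
#' @export
weighted_centroid <- function(volume, roi = NULL, subtract_floor = TRUE) {
  v <- if (is.null(roi)) volume else crop_volume(volume, roi$center, roi$size)
  w <- v$data
  if (subtract_floor) w <- w - min(w)
  tot <- sum(w)
  if (tot <= 0) stop("ROI carries no positive intensity after floor subtraction")
  c(sum(w * vol_axis_arr(v, 1)), sum(w * vol_axis_arr(v, 2)),
    sum(w * vol_axis_arr(v, 3))) / tot
}

vol_axis_arr <- function(vol, ax) {
  d <- dim(vol$data)
  x <- vol_axis(vol, ax)
  switch(ax,
         array(x, d),
         array(rep(x, each = d[1]), d),
         array(rep(x, each = d[1] * d[2]), d))
}

#' Displacement series of a tracked landmark
#'
#' @param time Frame times (s).
#' @param displacement n x 2 (lateral, elevational) or n x 3 matrix of
#'   displacements relative to the first frame (mm).
#' @return An object of class `displacement_series` (a data frame with
#'   `t_s`, `dx_mm`, `dy_mm`, optional `dz_mm`, `magnitude_mm`,
#'   `in_motion`).
#' @export
displacement_series <- function(time, displacement) {
  displacement <- rbind(displacement)
  stopifnot(length(time) == nrow(displacement), ncol(displacement) >= 2)
  df <- data.frame(t_s = time, dx_mm = displacement[, 1],
                   dy_mm = displacement[, 2])
  if (ncol(displacement) >= 3) df$dz_mm <- displacement[, 3]
  # magnitude over the lateral and elevational components only
  df$magnitude_mm <- sqrt(df$dx_mm^2 + df$dy_mm^2)
  df$in_motion <- FALSE
  class(df) <- c("displacement_series", "data.frame")
  df
}

#' Displacement series from a tracking log
#' @param log A `tracking_log` from [run_async_loop()].
#' @return A [displacement_series()].
#' @export
series_from_log <- function(log) {
  displacement_series(log$frames$t_s,
                      cbind(log$frames$residual_x_mm, log$frames$residual_y_mm,
                            log$frames$residual_z_mm))
}

#' Displacement series by reconstruction and centroiding
#'
#' Re-renders the tracked acquisition on a fine evaluation grid (0.1 mm
#' pitch) around the landmark and localises the landmark per frame by
#' weighted centroiding — the offline evaluation route, independent of the
#' geometric log.
#'
#' @param log A `tracking_log` from [run_async_loop()].
#' @param eval_pitch Evaluation voxel pitch (mm). Default 0.1.
#' @param render_size Edge length of the rendered evaluation volume (mm);
#'   must cover the residual excursion of the landmark. Default 10.
#' @param roi_size Edge of the centroiding region of interest (mm), tracked
#'   from frame to frame so it stays on the landmark. Default 2.6.
#' @param frame_stride Evaluate every k-th acquired frame. Default 1.
#' @param noise_sigma Rendering noise. Default 0.02.
#' @return A [displacement_series()].
#' @export
evaluate_residual_series <- function(log, eval_pitch = 0.1, render_size = 10,
                                     roi_size = 2.6, frame_stride = 1,
                                     noise_sigma = 0.02) {
  stopifnot(inherits(log, "tracking_log"))
  idx <- seq(1, nrow(log$frames), by = frame_stride)
  times <- log$frames$t_s[idx]
  lm0 <- log$scene$landmark_center
  grid <- centered_grid(lm0, render_size, eval_pitch)
  pos0 <- NULL
  roi_ctr <- lm0
  lim_lo <- grid$origin + roi_size / 2
  lim_hi <- grid$origin + (grid$shape - 1) * grid$pitch - roi_size / 2
  disp <- matrix(0, length(times), 2)
  for (k in seq_along(times)) {
    t <- times[k]
    pr <- log$probe
    pr$position <- c(log$frames$robot_x_mm[idx[k]], log$frames$robot_y_mm[idx[k]],
                     log$frames$robot_z_mm[idx[k]])
    sc <- scene_at_time(log$scene, log$profile, t)
    vol <- render_bmode(sc, pr, grid, log$psf, noise_sigma,
                        kinds = c("landmark", "lobe", "speckle"))
    # centroid a small ROI that follows the landmark between frames, so
    # surrounding speckle does not bias the estimate
    ctr <- weighted_centroid(vol, roi = list(center = roi_ctr, size = roi_size))
    roi_ctr <- pmin(pmax(ctr, lim_lo), lim_hi)
    if (k == 1) pos0 <- ctr
    disp[k, ] <- ctr[1:2] - pos0[1:2]
  }
  displacement_series(times, disp)
}

#' Detect onset and end of target motion
#'
#' The onset is the first frame whose displacement magnitude (lateral +
#' elevational) exceeds `threshold`; the end is the last such frame. All
#' frames in between are flagged in-motion.
#'
#' @param series A [displacement_series()].
#' @param threshold Onset threshold (mm). Default 0.1.
#' @return The series with `in_motion` filled in, plus attributes
#'   `onset_s` and `end_s` (both `NA` when the threshold is never
#'   exceeded).
#' @export
detect_onset <- function(series, threshold = 0.1) {
  stopifnot(inherits(series, "displacement_series"), threshold > 0)
  over <- which(series$magnitude_mm > threshold)
  series$in_motion <- FALSE
  if (length(over)) {
    win <- seq(min(over), max(over))
    series$in_motion[win] <- TRUE
    attr(series, "onset_s") <- series$t_s[min(over)]
    attr(series, "end_s") <- series$t_s[max(over)]
  } else {
    attr(series, "onset_s") <- NA_real_
    attr(series, "end_s") <- NA_real_
  }
  series
}

#' Residual-motion statistics over the in-motion window
#'
#' Mean and standard deviation of the displacement magnitude over frames
#' flagged in-motion, plus a `fraction_within(d)` function giving the share
#' of in-motion frames with magnitude below `d` mm.
#'
#' @param series A [displacement_series()] after [detect_onset()].
#' @return List with `mean_mm`, `sd_mm`, `n_frames`, `fraction_within`.
#' @export
residual_stats <- function(series) {
  stopifnot(inherits(series, "displacement_series"))
  m <- series$magnitude_mm[series$in_motion]
  if (!length(m)) stop("no in-motion frames; run detect_onset() first")
  list(mean_mm = mean(m), sd_mm = stats::sd(m), n_frames = length(m),
       fraction_within = function(d) mean(m < d))
}

#' Linear regression of mean residual against target speed
#'
#' Ordinary least squares through the per-speed mean residuals, as used to
#' extrapolate tracking performance beyond the tested speed range.
#'
#' @param means Data frame with columns `speed_mm_s` and `mean_residual_mm`
#'   (or a 2-column matrix).
#' @return List with `slope`, `intercept` and the fitted `lm` object.
#' @export
regress_residual_vs_speed <- function(means) {
  means <- as.data.frame(means)
  names(means)[1:2] <- c("speed_mm_s", "mean_residual_mm")
  if (nrow(means) < 2) stop("at least two speed levels are required")
  if (length(unique(means$speed_mm_s)) < 2)
    stop("speed levels must not be identical")
  fit <- stats::lm(mean_residual_mm ~ speed_mm_s, data = means)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit = fit)
}
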