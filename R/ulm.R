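#' Adaptive background and side-lobe suppression
#'
#' Zeroes every voxel whose intensity does not exceed both an adaptive
#' threshold — the Gaussian-weighted mean of its surrounding voxels
#' (centre excluded) — and a fixed empirical noise floor. Equality with
#' either threshold removes the voxel, so a uniform volume at the floor
#' value is fully zeroed.
#'
#' @param volume An [ulm_volume()].
#' @param noise_floor Empirical noise level (a.u.); `NULL` uses 3x the
#'   volume's standard deviation below its median (a background estimate).
#' @param kernel_size Odd edge length of the weighting neighbourhood.
#'   Default 5.
#' @param kernel_sigma Gaussian weight sigma in voxels. Default 1.
#' @return The suppressed `ulm_volume`.
#' @export
suppress_background <- function(volume, noise_floor = NULL, kernel_size = 5,
                                kernel_sigma = 1) {
  stopifnot(inherits(volume, "ulm_volume"), kernel_size %% 2 == 1)
  v <- volume$data
  if (is.null(noise_floor)) noise_floor <- 3 * stats::sd(v[v <= stats::median(v)])
  if (noise_floor < 0) stop("`noise_floor` must be non-negative")
  r <- (kernel_size - 1) / 2
  k1 <- exp(-0.5 * ((-r:r) / kernel_sigma)^2)
  # separable weighted sum, centre weight removed afterwards
  sm <- convolve_axis(convolve_axis(convolve_axis(v, k1, 1), k1, 2), k1, 3)
  w_tot <- sum(k1)^3
  w_ctr <- k1[r + 1]^3
  local_mean <- (sm - w_ctr * v) / (w_tot - w_ctr)
  keep <- (v > local_mean) & (v > noise_floor)
  out <- volume
  out$data <- ifelse(keep, v, 0)
  out
}

#' Estimate a PSF template from single-bubble patches
#'
#' Each patch is peak-normalised, aligned by shifting its intensity centre
#' of mass to the patch centre (trilinear resampling), averaged voxelwise,
#' and re-normalised to unit peak — the template later used for normalised
#' cross-correlation.
#'
#' @param patches List of >= 2 [ulm_volume()] patches of identical shape
#'   (typically 5 manually segmented bubbles).
#' @param allow_single Permit a single patch (no averaging). Default FALSE.
#' @return An object of class `psf_template` (an `ulm_volume` with unit
#'   peak).
#' @export
estimate_psf <- function(patches, allow_single = FALSE) {
  if (!is.list(patches) || inherits(patches, "ulm_volume")) patches <- list(patches)
  if (length(patches) < 2 && !allow_single)
    stop("at least two bubble patches are required (or set allow_single)")
  shapes <- vapply(patches, function(p) paste(dim(p$data), collapse = "x"), "")
  if (length(unique(shapes)) != 1) stop("patches must share one shape")
  d <- dim(patches[[1]]$data)
  ctr_vox <- (d - 1) / 2
  acc <- array(0, d)
  for (p in patches) {
    a <- p$data / max(p$data)
    com <- c(sum(a * slice_index(d, 1)), sum(a * slice_index(d, 2)),
             sum(a * slice_index(d, 3))) / sum(a)
    shift <- com - ctr_vox
    pts <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                                 z = seq_len(d[3]) - 1))
    pts <- sweep(pts, 2, shift, "+")
    s <- cpp_trilinear(as.numeric(a), d, pts, 0)
    acc <- acc + array(s$values, d)
  }
  acc <- acc / max(acc)
  out <- ulm_volume(acc, origin = -ctr_vox * patches[[1]]$pitch,
                    pitch = patches[[1]]$pitch)
  class(out) <- c("psf_template", class(out))
  out
}

slice_index <- function(d, ax) {
  switch(ax,
         array(seq_len(d[1]) - 1, d),
         array(rep(seq_len(d[2]) - 1, each = d[1]), d),
         array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d))
}

#' Normalised cross-correlation map against a PSF template
#'
#' Zero-normalised cross-correlation (Pearson correlation of the template
#' with each same-sized neighbourhood) computed with FFT-based running
#' sums. Scores lie in `[-1, 1]`; voxels within half a template of the
#' volume border are undefined (`NA`).
#'
#' @param volume An [ulm_volume()].
#' @param template A `psf_template` (or any `ulm_volume`), strictly smaller
#'   than `volume` and with nonzero variance.
#' @return An `ulm_volume` of correlation scores on `volume`'s grid.
#' @export
ncc_map <- function(volume, template) {
  stopifnot(inherits(volume, "ulm_volume"))
  tv <- template$data
  if (stats::sd(tv) == 0) stop("template has zero variance")
  vd <- dim(volume$data); td <- dim(tv)
  if (any(td > vd)) stop("template must be smaller than the volume")
  n <- prod(td)
  t0 <- tv - mean(tv)
  t_ss <- sum(t0^2)
  # correlate via FFT: pad both to volume size
  padded <- function(a) {
    p <- array(0, vd)
    p[seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3])] <- a
    p
  }
  V <- stats::fft(volume$data)
  V2 <- stats::fft(volume$data^2)
  Tc <- Conj(stats::fft(padded(t0)))
  Bc <- Conj(stats::fft(padded(array(1, td))))
  corr_num <- Re(stats::fft(V * Tc, inverse = TRUE)) / length(V)
  win_sum <- Re(stats::fft(V * Bc, inverse = TRUE)) / length(V)
  win_ss <- Re(stats::fft(V2 * Bc, inverse = TRUE)) / length(V)
  denom_sq <- pmax(win_ss - win_sum^2 / n, 0) * t_ss
  scores <- array(NA_real_, vd)
  ok <- denom_sq > 1e-12 * t_ss
  scores[ok] <- corr_num[ok] / sqrt(denom_sq[ok])
  scores <- pmin(1, pmax(-1, scores))
  scores <- array(scores, vd)
  # value at index i corresponds to the window starting at i; shift to the
  # window centre and invalidate borders
  half <- (td - 1) %/% 2
  centred <- array(NA_real_, vd)
  xr <- seq_len(vd[1] - td[1] + 1); yr <- seq_len(vd[2] - td[2] + 1)
  zr <- seq_len(vd[3] - td[3] + 1)
  centred[xr + half[1], yr + half[2], zr + half[3]] <-
    scores[xr, yr, zr]
  ulm_volume(centred, origin = volume$origin, pitch = volume$pitch,
             frame_time = volume$frame_time)
}

#' Sub-voxel bubble localisation from an NCC score map
#'
#' Finds strict 26-neighbourhood local maxima of the score map above
#' `threshold`, cubically interpolates the 3^3 neighbourhood of each peak
#' on a grid refined `upsample`-fold per axis, and returns the refined
#' maximum position in mm. Duplicate peaks within one voxel keep the higher
#' score.
#'
#' @param scores Score `ulm_volume` from [ncc_map()].
#' @param source Original intensity volume (for the `intensity` field);
#'   optional.
#' @param threshold Score threshold in `(0, 1]`. Default 0.5.
#' @param upsample Integer refinement factor >= 1. Default 5.
#' @param frame Frame index attached to the localisations. Default `NA`.
#' @return `data.frame` with columns `frame`, `x_mm`, `y_mm`, `z_mm`,
#'   `ncc`, `intensity` (empty when nothing exceeds the threshold).
#' @export
localise <- function(scores, source = NULL, threshold = 0.5, upsample = 5,
                     frame = NA_integer_) {
  stopifnot(threshold > 0, threshold <= 1, upsample >= 1,
            upsample == round(upsample))
  sd <- dim(scores$data)
  peaks <- cpp_local_maxima(as.numeric(scores$data), sd, threshold)
  empty <- data.frame(frame = integer(0), x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0), ncc = numeric(0), intensity = numeric(0))
  if (nrow(peaks) == 0) return(empty)
  # merge peaks within one voxel of each other, keeping the higher score
  vals <- scores$data[peaks]
  o <- order(-vals)
  peaks <- peaks[o, , drop = FALSE]; vals <- vals[o]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      later <- (i + 1):nrow(peaks)
      d <- pmax(abs(peaks[later, 1] - peaks[i, 1]),
                abs(peaks[later, 2] - peaks[i, 2]),
                abs(peaks[later, 3] - peaks[i, 3]))
      keep[later][d <= 1] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]; vals <- vals[keep]
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    sub_pos <- refine_peak(scores$data, p, upsample)
    pos_mm <- scores$origin + (p - 1 + sub_pos) * scores$pitch
    intensity <- if (is.null(source)) NA_real_ else source$data[p[1], p[2], p[3]]
    out[[i]] <- data.frame(frame = frame, x_mm = pos_mm[1], y_mm = pos_mm[2],
                           z_mm = pos_mm[3], ncc = vals[i],
                           intensity = intensity)
  }
  do.call(rbind, out)
}

# cubic (natural-spline) refinement of a 3^3 neighbourhood; returns the
# sub-voxel offset of the interpolated maximum, in voxels
refine_peak <- function(arr, p, upsample) {
  d <- dim(arr)
  rng <- lapply(1:3, function(ax) pmax(1L, pmin(d[ax], p[ax] + (-1:1))))
  nb <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  nb[is.na(nb)] <- min(nb, na.rm = TRUE)
  fine <- seq(-1, 1, length.out = 2L * upsample + 1L)
  coarse <- -1:1
  # separable spline interpolation along each axis
  a1 <- apply(nb, c(2, 3), function(v) stats::spline(coarse, v, xout = fine,
                                                     method = "natural")$y)
  a2 <- apply(a1, c(1, 3), function(v) stats::spline(coarse, v, xout = fine,
                                                     method = "natural")$y)
  # a2 dims: fine_y x fine_x x z3
  a3 <- apply(a2, c(1, 2), function(v) stats::spline(coarse, v, xout = fine,
                                                     method = "natural")$y)
  # a3 dims: fine_z x fine_y x fine_x
  best <- which(a3 == max(a3), arr.ind = TRUE)[1, ]
  offs <- c(fine[best[3]], fine[best[2]], fine[best[1]])
  # clamp at borders (degenerate neighbourhoods)
  pmin(pmax(offs, -1), 1)
}

#' Link per-frame localisations into tracks
#'
#' Gated, globally optimal per-frame-pair assignment: each active track
#' predicts its next position (constant velocity once two points are
#' available), candidate pairings beyond `max_speed / volume_rate` are
#' forbidden, and the Hungarian algorithm minimises the total
#' predicted-position distance. Unmatched detections seed new tracks;
#' tracks missing more than `max_gap` consecutive frames are closed.
#'
#' @param localisations `data.frame` from [localise()] rows over several
#'   frames (column `frame` must be populated), or a list of per-frame
#'   data frames.
#' @param volume_rate Acquisition rate (Hz).
#' @param max_speed Gating speed (mm/s). Default 10.
#' @param max_gap Frames a track may coast unmatched. Default 0.
#' @return `data.frame` with columns `track_id`, `frame`, `t_s`, `x_mm`,
#'   `y_mm`, `z_mm`, `speed_mm_s` (per-step speed; `NA` on each track's
#'   first point).
#' @export
link_tracks <- function(localisations, volume_rate, max_speed = 10,
                        max_gap = 0) {
  if (is.list(localisations) && !is.data.frame(localisations))
    localisations <- do.call(rbind, localisations)
  if (!nrow(localisations))
    return(data.frame(track_id = integer(0), frame = integer(0), t_s = numeric(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      speed_mm_s = numeric(0)))
  frames <- sort(unique(localisations$frame))
  gate <- max_speed / volume_rate
  active <- list()   # each: id, pts (matrix), frames, last_frame, vel
  done <- list()
  next_id <- 1L
  for (fr in frames) {
    det <- localisations[localisations$frame == fr, , drop = FALSE]
    P <- cbind(det$x_mm, det$y_mm, det$z_mm)
    nd <- nrow(P)
    # predictions
    np <- length(active)
    if (np && nd) {
      pred <- t(vapply(active, function(tr) {
        dt_frames <- fr - tr$last_frame
        if (is.null(tr$vel)) tr$pts[nrow(tr$pts), ] else
          tr$pts[nrow(tr$pts), ] + tr$vel * dt_frames
      }, numeric(3)))
      gates <- vapply(active, function(tr) gate * (fr - tr$last_frame), 0)
      C <- matrix(Inf, np, nd)
      for (i in seq_len(np)) {
        dd <- sqrt(colSums((t(P) - pred[i, ])^2))
        C[i, dd <= gates[i]] <- dd[dd <= gates[i]]
      }
      m <- hungarian_assign(C)
    } else {
      m <- integer(0)
    }
    matched_det <- rep(FALSE, nd)
    new_active <- list()
    for (i in seq_len(np)) {
      tr <- active[[i]]
      j <- if (length(m) >= i) m[i] else 0L
      if (j > 0) {
        matched_det[j] <- TRUE
        prev <- tr$pts[nrow(tr$pts), ]
        tr$pts <- rbind(tr$pts, P[j, ])
        tr$frames <- c(tr$frames, fr)
        tr$vel <- (P[j, ] - prev) / (fr - tr$last_frame)
        tr$last_frame <- fr
        new_active[[length(new_active) + 1L]] <- tr
      } else if (fr - tr$last_frame <= max_gap) {
        new_active[[length(new_active) + 1L]] <- tr
      } else {
        done[[length(done) + 1L]] <- tr
      }
    }
    for (j in which(!matched_det)) {
      new_active[[length(new_active) + 1L]] <-
        list(id = next_id, pts = rbind(P[j, ]), frames = fr, last_frame = fr,
             vel = NULL)
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  done <- c(done, active)
  rows <- lapply(done, function(tr) {
    n <- length(tr$frames)
    step_d <- c(NA_real_, sqrt(rowSums((tr$pts[-1, , drop = FALSE] -
                                        tr$pts[-n, , drop = FALSE])^2)))
    step_f <- c(NA_real_, diff(tr$frames))
    data.frame(track_id = tr$id, frame = tr$frames,
               t_s = (tr$frames - 1) / volume_rate,
               x_mm = tr$pts[, 1], y_mm = tr$pts[, 2], z_mm = tr$pts[, 3],
               speed_mm_s = step_d / step_f * volume_rate)
  })
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths)
# on an n x m cost matrix with Inf for forbidden pairs; returns, per row,
# the assigned column index or 0.
hungarian_assign <- function(C) {
  n <- nrow(C); m <- ncol(C)
  if (n == 0 || m == 0) return(integer(n))
  BIG <- 1e12
  Cf <- C
  Cf[!is.finite(Cf)] <- BIG
  # pad to square with BIG
  k <- max(n, m)
  M <- matrix(BIG, k, k)
  M[seq_len(n), seq_len(m)] <- Cf
  u <- numeric(k + 1); v <- numeric(k + 1)
  p <- integer(k + 1); way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, k)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(k)) {
        if (!used[j + 1]) {
          cur <- M[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:k) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(k)) {
    i <- p[j + 1]
    if (i >= 1 && i <= n && j <= m && is.finite(C[i, j])) assign[i] <- j
  }
  assign
}

#' Persistence filter
#'
#' Removes tracks shorter than `min_frames` localisations — spurious
#' detections rarely persist across frames, real bubbles do.
#'
#' @param tracks Track table from [link_tracks()].
#' @param min_frames Minimum localisations per track. Default 4.
#' @return The filtered track table.
#' @export
persistence_filter <- function(tracks, min_frames = 4) {
  stopifnot(min_frames >= 1)
  if (!nrow(tracks)) return(tracks)
  len <- table(tracks$track_id)
  keep <- names(len)[len >= min_frames]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Accumulate super-resolution density and speed maps
#'
#' Rasterises each track's interpolated polyline onto a fine grid: the
#' density map counts the number of distinct trajectories passing through
#' each voxel (at most one count per trajectory per voxel), and the speed
#' map averages the passing trajectories' local speeds.
#'
#' @param tracks Track table from [link_tracks()] /
#'   [persistence_filter()], motion-corrected to the reference frame.
#' @param grid A [volume_grid()], typically at 0.02 mm pitch.
#' @param count_per_visit Count every polyline sample instead of once per
#'   trajectory. Default FALSE.
#' @return An object of class `ulm_maps`: list with `density` and `speed`
#'   [ulm_volume()]s and the `grid`.
#' @export
accumulate_maps <- function(tracks, grid, count_per_visit = FALSE) {
  shape <- grid$shape
  dens <- array(0, shape)
  spd_sum <- array(0, shape)
  if (nrow(tracks)) {
    step <- min(grid$pitch) / 2
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, , drop = FALSE]
      tr <- tr[order(tr$frame), , drop = FALSE]
      pts <- cbind(tr$x_mm, tr$y_mm, tr$z_mm)
      if (nrow(pts) < 2) next
      samp <- list(); spd <- list()
      for (k in seq_len(nrow(pts) - 1)) {
        seg_len <- sqrt(sum((pts[k + 1, ] - pts[k, ])^2))
        ns <- max(2L, ceiling(seg_len / step) + 1L)
        a <- seq(0, 1, length.out = ns)
        samp[[k]] <- cbind(pts[k, 1] + a * (pts[k + 1, 1] - pts[k, 1]),
                           pts[k, 2] + a * (pts[k + 1, 2] - pts[k, 2]),
                           pts[k, 3] + a * (pts[k + 1, 3] - pts[k, 3]))
        spd[[k]] <- rep(tr$speed_mm_s[k + 1], ns)
      }
      samp <- do.call(rbind, samp); spdv <- unlist(spd)
      vox <- round(sweep(sweep(samp, 2, grid$origin, "-"), 2, grid$pitch, "/"))
      inb <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
        vox[, 1] < shape[1] & vox[, 2] < shape[2] & vox[, 3] < shape[3]
      vox <- vox[inb, , drop = FALSE]; spdv <- spdv[inb]
      if (!nrow(vox)) next
      lin <- 1 + vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3])
      if (count_per_visit) {
        tb <- tapply(rep(1, length(lin)), lin, sum)
        dens[as.integer(names(tb))] <- dens[as.integer(names(tb))] + as.numeric(tb)
        sb <- tapply(spdv, lin, sum)
        spd_sum[as.integer(names(sb))] <- spd_sum[as.integer(names(sb))] +
          as.numeric(sb)
      } else {
        sb <- tapply(spdv, lin, mean)    # trajectory's local speed per voxel
        ulin <- as.integer(names(sb))
        dens[ulin] <- dens[ulin] + 1
        spd_sum[ulin] <- spd_sum[ulin] + as.numeric(sb)
      }
    }
  }
  speed <- ifelse(dens > 0, spd_sum / pmax(dens, 1), 0)
  structure(list(
    density = ulm_volume(dens, grid$origin, grid$pitch),
    speed = ulm_volume(array(speed, shape), grid$origin, grid$pitch),
    grid = grid), class = "ulm_maps")
}

#' Smooth super-resolution maps for display
#'
#' The density map is convolved with a 3D Gaussian of 40 um full width at
#' half maximum; the speed map is mean-filtered over a spherical
#' (60 um diameter) neighbourhood restricted to perfused voxels
#' (density > 0).
#'
#' @param maps An `ulm_maps` object from [accumulate_maps()].
#' @param density_fwhm_um Gaussian FWHM for the density map (um).
#'   Default 40.
#' @param speed_ball_um Ball diameter for the speed map (um). Default 60.
#' @return The smoothed `ulm_maps`.
#' @export
smooth_maps <- function(maps, density_fwhm_um = 40, speed_ball_um = 60) {
  stopifnot(inherits(maps, "ulm_maps"))
  pitch_um <- maps$density$pitch * 1000
  sigma_vox <- density_fwhm_um * FWHM_TO_SIGMA / pitch_um
  out <- maps
  out$density$data <- gaussian_smooth3(maps$density$data, sigma_vox)
  # spherical mean filter on perfused voxels
  r_vox <- (speed_ball_um / 2) / pitch_um
  offs <- as.matrix(expand.grid(x = -ceiling(r_vox[1]):ceiling(r_vox[1]),
                                y = -ceiling(r_vox[2]):ceiling(r_vox[2]),
                                z = -ceiling(r_vox[3]):ceiling(r_vox[3])))
  inside <- rowSums(sweep(offs, 2, pmax(r_vox, 1e-9), "/")^2) <= 1
  offs <- offs[inside, , drop = FALSE]
  d <- dim(maps$speed$data)
  num <- array(0, d); cnt <- array(0, d)
  mask <- maps$density$data > 0
  sp <- maps$speed$data
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    src_x <- seq_len(d[1]) - o[1]; src_y <- seq_len(d[2]) - o[2]
    src_z <- seq_len(d[3]) - o[3]
    okx <- src_x >= 1 & src_x <= d[1]; oky <- src_y >= 1 & src_y <= d[2]
    okz <- src_z >= 1 & src_z <= d[3]
    num[okx, oky, okz] <- num[okx, oky, okz] +
      (sp * mask)[src_x[okx], src_y[oky], src_z[okz]]
    cnt[okx, oky, okz] <- cnt[okx, oky, okz] +
      mask[src_x[okx], src_y[oky], src_z[okz]]
  }
  sm <- ifelse(cnt > 0, num / pmax(cnt, 1), 0)
  out$speed$data <- array(ifelse(mask, sm, 0), d)
  out
}
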