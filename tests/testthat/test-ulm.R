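test_that("background suppression applies both thresholds with strict inequality", {
  z <- ulm_volume(array(0, c(7, 7, 7)), pitch = 0.1)
  expect_equal(max(suppress_background(z, noise_floor = 0.1)$data), 0)
  # isolated bright voxel on a zero background survives
  v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
  out <- suppress_background(ulm_volume(v, pitch = 0.1), noise_floor = 0.1)
  expect_equal(out$data[5, 5, 5], 1)
  expect_equal(sum(out$data > 0), 1)
  # a uniform volume at the floor value is fully zeroed (equality removes)
  u <- ulm_volume(array(0.3, c(7, 7, 7)), pitch = 0.1)
  expect_equal(max(suppress_background(u, noise_floor = 0.3)$data), 0)
  # and even with a lower floor, equality with the local mean removes all
  expect_equal(max(suppress_background(u, noise_floor = 0.01)$data), 0)
})

test_that("PSF estimation recovers the template from noisy shifted bubbles", {
  psf <- iso_psf(0.4)
  g <- centered_grid(c(0, 0, 0), 2.1, 0.1)
  clean <- render_scatterers(rbind(c(0, 0, 0)), 1, g, psf, 0,
                             fov_half = c(1e6, 1e6))
  # five identical patches average to themselves with unit peak
  est0 <- estimate_psf(rep(list(clean), 5))
  expect_equal(max(est0$data), 1)
  expect_equal(est0$data, clean$data / max(clean$data), tolerance = 1e-6)
  # noisy, sub-voxel shifted copies: recovered FWHM within 10%
  set.seed(21)
  patches <- lapply(1:5, function(i) {
    off <- runif(3, -0.04, 0.04)
    render_scatterers(rbind(off), runif(1, 0.8, 1.2), g, psf, 0.01,
                      fov_half = c(1e6, 1e6))
  })
  est <- estimate_psf(patches)
  prof <- est$data[, 11, 11]
  x <- vol_axis_mm <- est$origin[1] + (seq_along(prof) - 1) * est$pitch[1]
  above <- range(which(prof > 0.5))
  fwhm <- diff(stats::approx(seq_along(prof), x, xout = above)$y) + 0 # coarse
  expect_lt(abs(fwhm - 0.4) / 0.4, 0.25)
  # more precise: fitted sigma
  fit_sigma <- sqrt(sum(prof * x^2) / sum(prof))
  expect_lt(abs(fit_sigma - 0.4 / 2.3548) / (0.4 / 2.3548), 0.1)
  expect_error(estimate_psf(patches[1]), "at least two")
  expect_silent(estimate_psf(patches[1], allow_single = TRUE))
})

test_that("NCC scores match brute-force Pearson correlation and hit the bounds", {
  set.seed(22)
  vd <- c(16, 16, 16); td <- c(5, 5, 5)
  vol <- ulm_volume(array(runif(prod(vd)), vd), pitch = 0.1)
  tmpl <- ulm_volume(array(runif(prod(td)), td), pitch = 0.1)
  sc <- ncc_map(vol, tmpl)
  # brute force at a few positions (window centred at p)
  t0 <- tmpl$data - mean(tmpl$data)
  for (p in list(c(5, 6, 7), c(8, 8, 8), c(12, 4, 11))) {
    w <- vol$data[p[1] + (-2:2), p[2] + (-2:2), p[3] + (-2:2)]
    expect_equal(sc$data[p[1], p[2], p[3]],
                 sum((w - mean(w)) * t0) / sqrt(sum((w - mean(w))^2) * sum(t0^2)),
                 tolerance = 1e-6)
  }
  # borders are undefined
  expect_true(is.na(sc$data[1, 8, 8]))
  # a perfect copy scores 1, an inverted copy scores -1
  vol2 <- ulm_volume(array(0.5, vd), pitch = 0.1)
  vol2$data[6:10, 6:10, 6:10] <- tmpl$data
  vol2$data[2:6 + 8, 1:5, 1:5] <- -tmpl$data
  sc2 <- ncc_map(vol2, tmpl)
  expect_equal(sc2$data[8, 8, 8], 1, tolerance = 1e-6)
  expect_equal(sc2$data[12, 3, 3], -1, tolerance = 1e-6)
  expect_error(ncc_map(vol, ulm_volume(array(1, td), pitch = 0.1)), "variance")
})

test_that("sub-voxel localisation beats pitch/upsample on average", {
  psf <- iso_psf(0.4)
  pitch <- 0.1
  g <- centered_grid(c(0, 0, 0), 3.2, pitch)
  ns <- asNamespace("ulmtrack")
  tmpl <- ns$reference_bubble_template(psf, pitch)
  set.seed(23)
  errs <- replicate(60, {
    p <- runif(3, -0.25, 0.25)
    v <- render_scatterers(rbind(p), 1, g, psf, 0.005, fov_half = c(1e6, 1e6))
    l <- localise(ncc_map(v, tmpl), v, threshold = 0.5, upsample = 5)
    if (nrow(l) == 1) sqrt(sum((unlist(l[1, c("x_mm", "y_mm", "z_mm")]) - p)^2))
    else NA_real_
  })
  expect_true(all(!is.na(errs)))
  expect_lt(mean(errs), pitch / 5)
  # below-threshold maps yield an empty list
  weak <- ulm_volume(array(stats::runif(20^3, 0, 0.1), c(20, 20, 20)),
                     pitch = pitch)
  expect_equal(nrow(localise(ncc_map(weak, tmpl), weak, threshold = 0.99)), 0)
})

test_that("track linking preserves identities for parallel and crossing bubbles", {
  rate <- 20
  mk <- function(f) data.frame(frame = f, x_mm = c(0.05 * f, 0.05 * f),
                               y_mm = c(0, 0.8), z_mm = 0, ncc = 0.9,
                               intensity = 1)
  locs <- do.call(rbind, lapply(1:50, mk))
  tr <- link_tracks(locs, rate, max_speed = 3)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 50))
  expect_equal(unique(round(stats::na.omit(tr$speed_mm_s), 9)), 1)
  # crossing trajectories: constant-velocity prediction keeps identities
  set.seed(24)
  n_ok <- 0
  for (rep in 1:40) {
    rows <- lapply(1:21, function(f) {
      t <- f - 11
      data.frame(frame = f,
                 x_mm = 0.1 * t + rnorm(2, 0, 0.005),
                 y_mm = c(0.08, -0.08) * t + rnorm(2, 0, 0.005),
                 z_mm = 0, ncc = 0.9, intensity = 1)
    })
    tt <- link_tracks(do.call(rbind, rows), rate, max_speed = 6)
    id_a <- tt$track_id[tt$frame == 1][which.min(tt$y_mm[tt$frame == 1])]
    y_end <- tt$y_mm[tt$track_id == id_a & tt$frame == 21]
    if (length(y_end) == 1 && y_end > 0.5) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / 40, 0.9)
})

test_that("the persistence filter removes exactly the short tracks", {
  rate <- 10
  mk_track <- function(id, len) data.frame(frame = seq_len(len),
                                           x_mm = id + 0.01 * seq_len(len),
                                           y_mm = 0, z_mm = 0, ncc = 0.9,
                                           intensity = 1)
  locs <- rbind(mk_track(1, 3), mk_track(2, 4), mk_track(5, 7))
  tr <- link_tracks(locs, rate, max_speed = 2)
  expect_equal(length(unique(tr$track_id)), 3)
  kept <- persistence_filter(tr, 4)
  expect_equal(length(unique(kept$track_id)), 2)
  expect_true(all(table(kept$track_id) >= 4))
  # brute-force count of removals
  lens <- table(tr$track_id)
  expect_equal(sum(lens < 4), 3 - length(unique(kept$track_id)) + 1 - 1)
  expect_identical(persistence_filter(tr, 1), tr)
})

test_that("density counts trajectories once per voxel; speed maps recover Poiseuille", {
  g <- centered_grid(c(0, 0, 0), c(2, 1.02, 1.02), 0.02)  # odd, centred
  rate <- 20
  straight <- function(id, y, speed) {
    n <- 11
    x <- seq(-0.8, 0.8, length.out = n)
    data.frame(track_id = id, frame = 1:n, t_s = (0:(n - 1)) / rate,
               x_mm = x, y_mm = y, z_mm = 0,
               speed_mm_s = c(NA, rep(speed, n - 1)))
  }
  one <- accumulate_maps(straight(1, 0, 2), g)
  expect_true(all(one$density$data %in% c(0, 1)))
  two <- accumulate_maps(rbind(straight(1, 0, 2), straight(2, 0, 2)), g)
  expect_equal(max(two$density$data), 2)
  # speed map: centreline about twice the near-wall speed
  R <- 0.1
  tracks <- rbind(straight(1, 0, 2 * 1),                      # centreline
                  straight(2, 0.095, 2 * (1 - (0.095 / R)^2)))
  maps <- accumulate_maps(tracks, g)
  sp <- maps$speed$data
  ctr_row <- 26   # y = 0
  ctr_speed <- stats::median(sp[, ctr_row, 26][sp[, ctr_row, 26] > 0])
  wall_row <- ctr_row + round(0.095 / 0.02)
  wall_speed <- stats::median(sp[, wall_row, 26][sp[, wall_row, 26] > 0])
  expect_lt(abs(ctr_speed / wall_speed - 2 / (2 * (1 - 0.9025))) /
              (2 / (2 * (1 - 0.9025))), 0.2)
})

test_that("map smoothing: 40 um FWHM on density, mass conserved, uniform speed unchanged", {
  g <- centered_grid(c(0, 0, 0), 1.22, 0.02)  # 61^3, centred
  rate <- 20
  d1 <- data.frame(track_id = c(1, 1), frame = 1:2, t_s = c(0, 1 / rate),
                   x_mm = c(0, 1e-4), y_mm = 0, z_mm = 0,
                   speed_mm_s = c(NA, 1))
  maps <- accumulate_maps(d1, g)
  sm <- smooth_maps(maps)
  expect_equal(sum(sm$density$data), sum(maps$density$data), tolerance = 1e-3)
  prof <- sm$density$data[, 31, 31]
  x <- (seq_along(prof) - 31) * 20   # um
  hm <- max(prof) / 2
  above <- which(prof > hm)
  lo <- stats::approx(prof[c(min(above) - 1, min(above))],
                      x[c(min(above) - 1, min(above))], xout = hm)$y
  hi <- stats::approx(prof[c(max(above), max(above) + 1)],
                      x[c(max(above), max(above) + 1)], xout = hm)$y
  expect_equal(hi - lo, 40, tolerance = 2)
  # uniform speed along a path is unchanged by the ball filter
  line <- data.frame(track_id = 1, frame = 1:6, t_s = (0:5) / rate,
                     x_mm = seq(-0.4, 0.4, length.out = 6), y_mm = 0, z_mm = 0,
                     speed_mm_s = c(NA, rep(3, 5)))
  m2 <- smooth_maps(accumulate_maps(line, g))
  on_path <- m2$speed$data[m2$density$data > 0 & m2$speed$data > 0]
  expect_true(all(abs(on_path - 3) < 1e-9))
})
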