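test_that("rigid transforms compose, invert and round-trip points", {
  tf <- rigid_transform(c(1, -2, 0.5), c(10, -5, 7), center = c(1, 1, 20))
  inv <- invert_transform(tf)
  set.seed(1)
  pts <- matrix(runif(30, -5, 5), ncol = 3)
  back <- transform_points(inv, transform_points(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  comp <- compose_transforms(inv, tf)
  expect_lt(max(abs(transform_points(comp, pts) - pts)), 1e-9)
})

test_that("translation-only registration recovers known shifts", {
  sp <- speckle_volume(11, n = 32, pitch = 0.4, npts = 300, psf = iso_psf(0.9))
  same <- estimate_translation(sp$vol, sp$vol)
  expect_lt(max(abs(same$transform$translation)), 0.01)
  shift <- c(1.2, -0.8, 0.4)
  mov <- transformed_speckle(sp, rigid_transform(shift))
  est <- estimate_translation(sp$vol, mov)
  expect_lt(max(abs(est$transform$translation - shift)), 0.1 * 0.4)
  expect_equal(est$transform$rotation, c(0, 0, 0))
})

test_that("the pyramid rescues shifts beyond the single-level basin", {
  sp <- speckle_volume(12, n = 40, pitch = 0.4, npts = 500, psf = iso_psf(0.9))
  shift <- c(5, 0, 0)   # > 10 voxels
  mov <- transformed_speckle(sp, rigid_transform(shift))
  single <- estimate_translation(sp$vol, mov, n_pyramid_levels = 1,
                                 coarse_search = FALSE)
  pyr <- estimate_translation(sp$vol, mov, n_pyramid_levels = 4)
  expect_gt(max(abs(single$transform$translation - shift)), 0.4)
  expect_lt(max(abs(pyr$transform$translation - shift)), 0.1)
  # flat volumes are flagged as non-convergent
  flat <- ulm_volume(array(1, c(8, 8, 8)), pitch = 1)
  expect_false(estimate_translation(flat, flat)$converged)
})

test_that("LM rigid registration recovers a known 2 mm / 3 degree motion", {
  sp <- speckle_volume(13, n = 56, pitch = 0.1, npts = 600)
  tf <- rigid_transform(c(1.2, -1.1, 0.8), c(3, -2, 1.5), center = c(0, 0, 0))
  mov <- transformed_speckle(sp, tf)
  # documented recipe for large motions: translation pyramid first, then LM
  t0 <- estimate_translation(sp$vol, mov, n_pyramid_levels = 4)
  est <- estimate_rigid_lm(sp$vol, mov,
                           init = rigid_transform(t0$transform$translation,
                                                  center = c(0, 0, 0)))
  expect_lt(max(abs(est$transform$translation - tf$translation)), 0.05)
  expect_lt(max(abs(est$transform$rotation - tf$rotation)), 0.1)
  # optimiser at least as good as the truth on noiseless data
  ns <- asNamespace("ulmtrack")
  cost_true <- ns$ssd_cost(sp$vol, mov, tf)
  expect_lte(est$final_cost, cost_true + 1e-6)
})

test_that("LM started at the truth stops immediately; warm starts converge faster", {
  sp <- speckle_volume(14, n = 40, pitch = 0.1, npts = 300)
  tf <- rigid_transform(c(0.5, -0.3, 0.2), c(1, 0.5, -1), center = c(0, 0, 0))
  mov <- transformed_speckle(sp, tf)
  at_truth <- estimate_rigid_lm(sp$vol, mov, init = tf, n_pyramid_levels = 1)
  expect_lte(at_truth$n_iterations, 2)
  expect_lt(max(abs(at_truth$transform$translation - tf$translation)), 0.02)
  # smooth motion sequence: warm start needs fewer iterations than identity
  tf2 <- rigid_transform(tf$translation + c(0.06, 0.04, 0), tf$rotation,
                         center = c(0, 0, 0))
  mov2 <- transformed_speckle(sp, tf2)
  warm <- estimate_rigid_lm(sp$vol, mov2, init = tf, n_pyramid_levels = 1)
  cold <- estimate_rigid_lm(sp$vol, mov2,
                            init = rigid_transform(center = c(0, 0, 0)),
                            n_pyramid_levels = 1)
  expect_lt(warm$n_iterations, cold$n_iterations)
  expect_lt(max(abs(warm$transform$translation - tf2$translation)), 0.05)
})

test_that("translation-only and 6-DoF estimates agree on pure translations", {
  sp <- speckle_volume(15, n = 40, pitch = 0.1, npts = 300)
  shift <- c(0.7, -0.4, 0.25)
  mov <- transformed_speckle(sp, rigid_transform(shift))
  t3 <- estimate_translation(sp$vol, mov)$transform$translation
  t6 <- estimate_rigid_lm(sp$vol, mov)$transform$translation
  expect_lt(max(abs(t3 - t6)), 0.05)
})

test_that("resampling: identity is exact, integer shifts are index shifts, round trips recover", {
  sp <- speckle_volume(16, n = 24, pitch = 0.2, npts = 150, psf = iso_psf(0.5))
  v <- sp$vol
  id <- resample_volume(v, rigid_transform())
  expect_equal(id$data, v$data)
  shifted <- resample_volume(v, rigid_transform(c(0.4, 0, 0)))  # 2 voxels
  d <- dim(v$data)
  expect_equal(shifted$data[1:(d[1] - 2), , ], v$data[3:d[1], , ])
  # shift then inverse shift recovers away from borders; trilinear
  # interpolation attenuates content near its own band limit, so the bound
  # is checked on smooth content at the level linear interpolation achieves
  sm <- speckle_volume(17, n = 32, pitch = 0.2, npts = 60, psf = iso_psf(2.4))
  sh <- c(0.13, -0.07, 0.22)
  back <- resample_volume(resample_volume(sm$vol, rigid_transform(sh)),
                          rigid_transform(-sh))
  core <- 5:28
  expect_lt(max(abs(back$data[core, core, core] - sm$vol$data[core, core, core])),
            0.02 * max(sm$vol$data))
})

test_that("Lagrangian accumulation concentrates a moving point only under the right transforms", {
  g <- centered_grid(c(0, 0, 0), 6, 0.2)
  psf <- iso_psf(0.5)
  shifts <- seq(-1.5, 1.5, length.out = 7)
  frames <- lapply(shifts, function(s)
    render_scatterers(rbind(c(s, 0, 0)), 1, g, psf, 0, fov_half = c(1e6, 1e6)))
  tfs <- lapply(shifts, function(s) rigid_transform(c(s, 0, 0)))
  ids <- lapply(shifts, function(s) rigid_transform())
  corrected <- lagrangian_accumulate(frames, tfs, reducer = "mean")
  smeared <- lagrangian_accumulate(frames, ids, reducer = "mean")
  above <- function(v) sum(v$data > 0.5 * max(v$data))
  expect_lt(above(corrected), 30)       # a single concentrated blob
  expect_gt(above(smeared), 2 * above(corrected))  # motion smear
  peak <- which(corrected$data == max(corrected$data), arr.ind = TRUE)[1, ]
  pos <- corrected$origin + (peak - 1) * corrected$pitch
  expect_lt(max(abs(pos - c(0, 0, 0))), 0.21)
  # identity transforms with mean reducer = temporal mean
  tm <- lagrangian_accumulate(frames, ids, reducer = "mean")
  ref <- Reduce(`+`, lapply(frames, `[[`, "data")) / length(frames)
  core <- 5:26
  expect_equal(tm$data[core, core, core], ref[core, core, core],
               tolerance = 1e-6)
  expect_error(lagrangian_accumulate(frames[1:3], tfs), "one transform")
})
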