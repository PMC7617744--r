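test_that("two-wavelength voxel pitch follows from frequency and sound speed", {
  expect_equal(voxel_pitch_two_wavelengths(probe_model()), 0.3948718,
               tolerance = 1e-6)
  expect_equal(round(voxel_pitch_two_wavelengths(probe_model()), 1), 0.4)
  p2 <- probe_model(center_frequency = 1, sound_speed = 1500)
  expect_equal(voxel_pitch_two_wavelengths(p2), 3.0)
  # dimensional-analysis oracle: (m/s) / (1/s) -> m -> mm, twice
  probe <- probe_model()
  lam_mm <- probe$sound_speed / (probe$center_frequency * 1e6) * 1e3
  expect_equal(voxel_pitch_two_wavelengths(probe), 2 * lam_mm)
})

test_that("a single scatterer renders at the right place with the right mass", {
  g <- centered_grid(c(0, 0, 20), 4.1, 0.1)   # odd voxel count: centred
  psf <- iso_psf(0.4)
  v <- render_scatterers(rbind(c(0, 0, 20)), 2, g, psf, 0)
  peak <- which(v$data == max(v$data), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(peak), (dim(v$data) + 1) / 2)
  # integral equals amplitude x Gaussian normalisation to 1%
  sig <- psf$fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(sum(v$data) * prod(v$pitch), 2 * (2 * pi)^1.5 * prod(sig),
               tolerance = 0.01)
})

test_that("scatterers outside the field of view vanish from the image", {
  g <- centered_grid(c(0, 0, 20), c(14, 6, 6), 0.2)
  psf <- iso_psf(0.4)
  inside <- render_scatterers(rbind(c(0, 0, 20)), 1, g, psf, 0,
                              fov_half = c(5, 5))
  outside <- render_scatterers(rbind(c(6.5, 0, 20)), 1, g, psf, 0,
                               fov_half = c(5, 5))
  expect_lt(max(outside$data), 1e-3 * max(inside$data))
  # scene-level: landmark beyond the FoV is absent from the B-mode volume
  sc <- tiny_scene(seed = 2, n_speckle = 0, n_bubbles = 0)
  probe <- default_probe()
  grid <- centered_grid(sc$landmark_center, 6, 0.4)
  v_in <- render_bmode(sc, probe, grid, default_psf(probe))
  sc_out <- sc
  sc_out$displacement <- c(14, 0, 0)   # rigid shift far beyond the FoV
  grid_fixed <- centered_grid(sc$landmark_center, 6, 0.4)
  v_out <- render_bmode(sc_out, probe, grid_fixed, default_psf(probe))
  expect_lt(max(v_out$data), 1e-3 * max(v_in$data))
})

test_that("noiseless rendering is shift-equivariant for integer voxel shifts", {
  g <- centered_grid(c(0, 0, 20), 6, 0.2)
  psf <- iso_psf(0.4)
  set.seed(9)
  pos <- cbind(runif(40, -1.5, 1.5), runif(40, -1.5, 1.5), runif(40, 18.5, 21.5))
  amp <- runif(40)
  v1 <- render_scatterers(pos, amp, g, psf, 0, fov_half = c(1e6, 1e6))
  v2 <- render_scatterers(sweep(pos, 2, c(0.4, 0, 0), "+"), amp, g, psf, 0,
                          fov_half = c(1e6, 1e6))
  d <- dim(v1$data)
  expect_lt(max(abs(v2$data[3:d[1], , ] - v1$data[1:(d[1] - 2), , ])),
            1e-6 * max(v1$data))
})

test_that("contrast rendering suppresses tissue except for configured leakage", {
  sc <- tiny_scene(seed = 3, n_speckle = 100, n_bubbles = 0)
  probe <- default_probe()
  grid <- centered_grid(c(0, 0, 20), 8, 0.4)
  psf <- default_psf(probe)
  v0 <- render_contrast(sc, probe, grid, psf, 0, leakage = 0)
  expect_equal(max(v0$data), 0)
  v1 <- render_contrast(sc, probe, grid, psf, 0, leakage = 0.2)
  expect_gt(max(v1$data), 0)
})

test_that("acquisition emits uniformly spaced frames with floor(rate x duration) count", {
  sc <- tiny_scene(seed = 1, n_speckle = 0, n_bubbles = 0)
  probe <- default_probe()
  grid <- volume_grid(c(0, 0, 19), 1, c(2, 2, 2))
  psf <- default_psf(probe)
  seq1 <- acquire_sequence(sc, NULL, probe, grid, psf, volume_rate = 85,
                           duration = 1)
  expect_length(seq1, 85)
  tt <- vapply(seq1, `[[`, 0, "frame_time")
  expect_equal(diff(tt), rep(1 / 85, 84))
  expect_length(acquire_sequence(sc, NULL, probe, grid, psf,
                                 volume_rate = 85, duration = 70), 5950)
})

test_that("the delay-and-sum round trip localises point targets to a voxel", {
  probe <- default_probe()
  g <- centered_grid(c(0, 0, 20), c(6, 6, 6), 0.4)
  v <- das_point_roundtrip(rbind(c(0, 0, 20)), probe, g)
  peak <- which(v$data == max(v$data), arr.ind = TRUE)[1, ]
  pos <- v$origin + (peak - 1) * v$pitch
  expect_true(all(abs(pos - c(0, 0, 20)) <= v$pitch + 1e-9))
  # shift equivariance: move the target 1 mm laterally
  v2 <- das_point_roundtrip(rbind(c(1, 0, 20)), probe, g)
  peak2 <- which(v2$data == max(v2$data), arr.ind = TRUE)[1, ]
  pos2 <- v2$origin + (peak2 - 1) * v2$pitch
  expect_true(all(abs(pos2 - c(1, 0, 20)) <= v2$pitch + 1e-9))
  # two targets 2 mm apart give two distinct peaks
  v3 <- das_point_roundtrip(rbind(c(-1, 0, 20), c(1, 0, 20)), probe, g)
  mx <- max(v3$data)
  lm <- ulmtrack:::cpp_local_maxima(as.numeric(v3$data), dim(v3$data), 0.5 * mx)
  pk_mm <- sweep(sweep(lm - 1, 2, v3$pitch, "*"), 2, v3$origin, "+")
  near1 <- any(sqrt(rowSums(sweep(pk_mm, 2, c(-1, 0, 20), "-")^2)) <= 0.6)
  near2 <- any(sqrt(rowSums(sweep(pk_mm, 2, c(1, 0, 20), "-")^2)) <= 0.6)
  expect_true(near1 && near2)
  expect_error(das_point_roundtrip(rbind(c(0, 0, -5)), probe, g), "front")
})
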