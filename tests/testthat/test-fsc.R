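# construct two half-maps sharing structure up to a known band limit: a
# common broadband blob field plus strong independent noise high-passed at
# the cutoff frequency, so the shells decorrelate right at the limit
bandlimited_pair <- function(band_limit_um, n = 64, pitch = 0.02,
                             seeds = c(1, 2)) {
  d <- rep(n, 3)
  set.seed(99)
  base <- array(0, d)
  idx <- cbind(sample(5:(n - 5), 80, TRUE), sample(5:(n - 5), 80, TRUE),
               sample(5:(n - 5), 80, TRUE))
  base[idx] <- 10
  base <- ulmtrack:::gaussian_smooth3(base, rep(0.7, 3))
  fb <- 1 / (d * pitch)
  f <- lapply(1:3, function(ax) {
    k <- seq_len(d[ax]) - 1
    pmin(k, d[ax] - k) * fb[ax]
  })
  fr <- sqrt(outer(outer(f[[1]]^2, f[[2]]^2, "+"), f[[3]]^2, "+"))
  fc <- 1000 / band_limit_um
  half <- function(seed) {
    set.seed(seed)
    X <- stats::fft(array(stats::rnorm(prod(d), 0, 30), d))
    X[fr <= fc] <- 0
    ulm_volume(base + Re(stats::fft(X, inverse = TRUE)) / prod(d),
               origin = c(0, 0, 0), pitch = pitch)
  }
  list(a = half(seeds[1]), b = half(seeds[2]))
}

test_that("odd/even track split partitions the density mass", {
  g <- centered_grid(c(0, 0, 0), c(2, 1, 0.4), 0.02)
  rate <- 20
  mk <- function(id, y) data.frame(track_id = id, frame = 1:6,
                                   t_s = (0:5) / rate,
                                   x_mm = seq(-0.8, 0.8, length.out = 6),
                                   y_mm = y, z_mm = 0,
                                   speed_mm_s = c(NA, rep(1, 5)))
  tracks <- do.call(rbind, lapply(1:10, function(i) mk(i, -0.4 + i * 0.07)))
  halves <- split_odd_even(tracks, g)
  expect_equal(length(unique(tracks$track_id[tracks$track_id %in%
                                               seq(1, 9, 2)])), 5)
  full <- accumulate_maps(tracks, g)
  expect_equal(sum(halves$odd$density$data) + sum(halves$even$density$data),
               sum(full$density$data))
  expect_lt(abs(sum(halves$odd$density$data) / sum(full$density$data) - 0.5),
            0.1)
  expect_error(split_odd_even(mk(1, 0), g), "at least two")
})

test_that("FSC of a volume with itself is one everywhere and symmetric", {
  set.seed(31)
  v <- ulm_volume(array(runif(24^3), c(24, 24, 24)), pitch = 0.02)
  cv <- fsc_curve(v, v)
  expect_true(all(abs(cv$correlation[cv$defined] - 1) < 1e-9))
  r <- fsc_resolution(cv)
  expect_false(r$crossed)
  expect_equal(r$resolution_um, 2 * 0.02 * 1000)  # grid Nyquist sentinel
  # symmetry
  set.seed(32)
  w <- ulm_volume(array(runif(24^3), c(24, 24, 24)), pitch = 0.02)
  expect_equal(fsc_curve(v, w)$correlation, fsc_curve(w, v)$correlation)
})

test_that("independent noise volumes decorrelate within the null bound", {
  set.seed(33)
  a <- ulm_volume(array(rnorm(48^3), c(48, 48, 48)), pitch = 0.02)
  b <- ulm_volume(array(rnorm(48^3), c(48, 48, 48)), pitch = 0.02)
  cv <- fsc_curve(a, b)
  ok <- cv$defined & cv$shell > 0
  frac <- mean(abs(cv$correlation[ok]) < 3 / sqrt(cv$n_voxels[ok]))
  expect_gte(frac, 0.95)
})

test_that("the half-bit threshold has its closed form, limits and monotonicity", {
  expect_equal(halfbit_threshold(1e12), 0.2071 / 1.2071, tolerance = 1e-4)
  expect_equal(halfbit_threshold(1),
               (0.2071 + 1.9102) / (1.2071 + 0.9102))
  nseq <- unique(round(10^seq(0, 6, by = 0.1)))
  expect_true(all(diff(halfbit_threshold(nseq)) < 0))
  # FSC shells use the matching per-shell counts
  set.seed(34)
  v <- ulm_volume(array(runif(16^3), c(16, 16, 16)), pitch = 0.02)
  cv <- fsc_curve(v, v)
  expect_equal(cv$threshold, halfbit_threshold(cv$n_voxels))
})

test_that("a known band limit is recovered within one shell width", {
  shell_w <- 1 / (64 * 0.02)  # cycles/mm
  for (bl in c(60, 100, 160)) {
    pr <- bandlimited_pair(bl)
    r <- fsc_resolution(fsc_curve(pr$a, pr$b))
    expect_true(r$crossed)
    fc <- 1000 / bl
    expect_lt(abs(r$crossing_freq_cyc_per_mm - fc), shell_w + 1e-9)
  }
})

test_that("extra independent noise on both half-maps never improves resolution", {
  pr <- bandlimited_pair(100)
  r0 <- fsc_resolution(fsc_curve(pr$a, pr$b))$resolution_um
  for (s in 1:3) {
    set.seed(40 + s)
    na_ <- pr$a; nb <- pr$b
    na_$data <- na_$data + array(rnorm(length(na_$data), 0, 2), dim(na_$data))
    nb$data <- nb$data + array(rnorm(length(nb$data), 0, 2), dim(nb$data))
    r1 <- fsc_resolution(fsc_curve(na_, nb))$resolution_um
    expect_gte(r1, r0 - 1e-9)
  }
})
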