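# shared fixtures: all synthetic, built in code at test time

iso_psf <- function(fwhm = 0.4) psf_model(fwhm = rep(fwhm, 3))

# speckle volume from seeded random scatterers; returns volume + scatterers
speckle_volume <- function(seed, n = 48, pitch = 0.1, npts = 400,
                           psf = iso_psf(), noise = 0) {
  set.seed(seed)
  g <- centered_grid(c(0, 0, 0), n * pitch, pitch)
  pos <- matrix(stats::runif(3 * npts, -n * pitch / 2, n * pitch / 2), ncol = 3)
  amp <- sqrt(-2 * log(stats::runif(npts)))
  list(vol = render_scatterers(pos, amp, g, psf, noise, fov_half = c(1e6, 1e6)),
       pos = pos, amp = amp, grid = g, psf = psf)
}

# render the same scatterers after a rigid transform of the object
transformed_speckle <- function(sp, tf, noise = 0) {
  render_scatterers(transform_points(tf, sp$pos), sp$amp, sp$grid, sp$psf,
                    noise, fov_half = c(1e6, 1e6))
}

# numeric displacement oracle: trapezoid-rule integration of the speed
# profile at tiny time steps (the speed is piecewise linear, so the rule is
# exact except for O(accel * dt^2) error at the three switching instants)
integrate_trapezoid <- function(seg, t_end, dt = 1e-5) {
  tt <- seq(seg$start_time, t_end, by = dt)
  if (length(tt) < 2) return(0)
  v <- trapezoid_velocity(tt, seg)
  sum((utils::head(v, -1) + utils::tail(v, -1)) / 2 * dt) +
    trapezoid_velocity(t_end, seg) * (t_end - tt[length(tt)])
}

default_probe <- function() probe_model()

tiny_scene <- function(seed = 1, n_speckle = 200, n_bubbles = 6, ...) {
  phantom_scene(n_speckle = n_speckle, n_bubbles = n_bubbles, seed = seed, ...)
}
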