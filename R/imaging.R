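#' Virtual matrix-array probe
#'
#' Geometry and pose of the volumetric imaging probe. The pose is a
#' probe-frame offset (mm) plus a rotation about the depth axis (deg) —
#' rotating the probe about depth is how the lateral protocol is remapped
#' onto the elevational or diagonal directions.
#'
#' @param aperture Aperture extent (lateral, elevational) in mm.
#' @param n_elements Element counts (lateral, elevational).
#' @param center_frequency Centre frequency (MHz). Default 7.8.
#' @param sound_speed Speed of sound (m/s). Default 1540.
#' @param position Probe-frame offset of the probe (mm 3-vector).
#' @param rotation_deg Rotation about the depth axis (deg).
#' @return An object of class `probe_model`.
#' @export
probe_model <- function(aperture = c(9.6, 10.6), n_elements = c(32, 32),
                        center_frequency = 7.8, sound_speed = 1540,
                        position = c(0, 0, 0), rotation_deg = 0) {
  stopifnot(center_frequency > 0, sound_speed > 0)
  structure(list(aperture = aperture, n_elements = as.integer(n_elements),
                 center_frequency = center_frequency, sound_speed = sound_speed,
                 position = as.numeric(position), rotation_deg = rotation_deg),
            class = "probe_model")
}

#' Wavelength of a probe (mm)
#' @param probe A [probe_model()].
#' @return Wavelength in mm.
#' @export
probe_wavelength <- function(probe) {
  probe$sound_speed / (probe$center_frequency * 1e6) * 1e3
}

#' Two-wavelength voxel pitch (mm)
#'
#' The online beamforming grid uses voxels of two wavelengths per side; at
#' 7.8 MHz in 1540 m/s tissue this is 0.395 mm, i.e. 0.4 mm to header
#' precision.
#'
#' @param probe A [probe_model()].
#' @return Pitch in mm.
#' @export
voxel_pitch_two_wavelengths <- function(probe) {
  2 * probe_wavelength(probe)
}

#' Imaging point-spread function model
#'
#' Anisotropic Gaussian blob with optional side-lobe replicas parallel to
#' the main lobe (the matrix array's uneven element layout produces weak
#' parallel copies of strong reflectors).
#'
#' @param fwhm Full width at half maximum per axis (lateral, elevational,
#'   axial) in mm.
#' @param sidelobe_amplitude Fraction of the main-lobe amplitude in
#'   `[0, 1)`. Default 0 (off).
#' @param sidelobe_offset Offset of the replicas (mm). Default 1.5.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(fwhm = c(0.41, 0.37, 0.39), sidelobe_amplitude = 0,
                      sidelobe_offset = 1.5) {
  stopifnot(all(fwhm > 0), sidelobe_amplitude >= 0, sidelobe_amplitude < 1)
  structure(list(fwhm = rep(fwhm, length.out = 3L),
                 sidelobe_amplitude = sidelobe_amplitude,
                 sidelobe_offset = sidelobe_offset),
            class = "psf_model")
}

#' Default PSF for a probe at a reference depth
#'
#' Diffraction heuristic: lateral/elevational FWHM = wavelength x depth /
#' aperture, axial FWHM = two wavelengths.
#'
#' @param probe A [probe_model()].
#' @param depth Reference depth (mm). Default 20.
#' @param ... Passed to [psf_model()].
#' @return A [psf_model()].
#' @export
default_psf <- function(probe, depth = 20, ...) {
  lam <- probe_wavelength(probe)
  psf_model(fwhm = c(lam * depth / probe$aperture[1],
                     lam * depth / probe$aperture[2],
                     2 * lam), ...)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

# world -> probe frame
world_to_probe <- function(pts, probe) {
  th <- -probe$rotation_deg * pi / 180
  p <- sweep(pts, 2, probe$position, "-")
  cbind(cos(th) * p[, 1] - sin(th) * p[, 2],
        sin(th) * p[, 1] + cos(th) * p[, 2],
        p[, 3])
}

#' Render an arbitrary scatterer table
#'
#' Low-level forward model behind [render_bmode()] / [render_contrast()]:
#' splats probe-frame point scatterers as PSF-shaped Gaussian blobs onto a
#' grid, with field-of-view directivity roll-off, optional side-lobe
#' replicas and additive Gaussian noise.
#'
#' @param pos n x 3 matrix of probe-frame positions (mm).
#' @param amp Scatterer amplitudes (length n).
#' @param grid A [volume_grid()].
#' @param psf A [psf_model()].
#' @param noise_sigma Additive Gaussian noise scale. Default 0.
#' @param fov_half Field-of-view half-widths (lateral, elevational) in mm.
#' @param fov_rolloff_sigma Gaussian taper scale beyond the field of view
#'   (mm). Default 0.4.
#' @param frame_time Timestamp for the output volume.
#' @return An [ulm_volume()].
#' @export
render_scatterers <- function(pos, amp, grid, psf, noise_sigma = 0,
                              fov_half = c(7.5, 7.5), fov_rolloff_sigma = 0.4,
                              frame_time = 0) {
  render_points(rbind(pos), amp, grid, psf, noise_sigma, fov_half,
                fov_rolloff_sigma, frame_time)
}

render_points <- function(pos, amp, grid, psf, noise_sigma = 0,
                          fov_half = c(7.5, 7.5), fov_rolloff_sigma = 0.4,
                          frame_time = 0) {
  shape <- grid$shape
  sig <- psf$fwhm * FWHM_TO_SIGMA
  if (nrow(pos)) {
    # directivity roll-off outside the configured field of view
    ex <- pmax(0, abs(pos[, 1]) - fov_half[1])
    ey <- pmax(0, abs(pos[, 2]) - fov_half[2])
    w <- exp(-0.5 * ((ex^2 + ey^2) / fov_rolloff_sigma^2) * 2)
    amp <- amp * w
    keep <- amp > 0
    pos <- pos[keep, , drop = FALSE]
    amp <- amp[keep]
  }
  if (nrow(pos)) {
    if (psf$sidelobe_amplitude > 0) {
      reps <- list(c(psf$sidelobe_offset, 0, 0), c(-psf$sidelobe_offset, 0, 0),
                   c(0, psf$sidelobe_offset, 0), c(0, -psf$sidelobe_offset, 0))
      extra_pos <- do.call(rbind, lapply(reps, function(o) sweep(pos, 2, o, "+")))
      pos <- rbind(pos, extra_pos)
      amp <- c(amp, rep(amp * psf$sidelobe_amplitude, length(reps)))
    }
    sigma <- matrix(sig, nrow(pos), 3, byrow = TRUE)
    data <- cpp_render_gaussians(shape, grid$origin, grid$pitch, pos, amp,
                                 sigma, 4.5)
  } else {
    data <- numeric(prod(shape))
  }
  vol <- array(data, dim = shape)
  if (noise_sigma > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sigma), dim = shape)
  ulm_volume(vol, origin = grid$origin, pitch = grid$pitch,
             frame_time = frame_time)
}

#' Render a B-mode volume of a scene
#'
#' Image-domain forward model: every scatterer inside the field of view is
#' splatted as an anisotropic Gaussian blob with the PSF's widths (plus
#' optional side-lobe replicas); amplitudes outside the footprint roll off
#' with a Gaussian directivity taper, so targets beyond the field of view
#' vanish from the image. Additive half-normal noise models the envelope
#' noise floor.
#'
#' @param scene A [phantom_scene()] (typically from [scene_at_time()]).
#' @param probe A [probe_model()] (pose determines the frame).
#' @param grid A [volume_grid()] in the probe frame.
#' @param psf A [psf_model()].
#' @param noise_sigma Noise scale (a.u.). Default 0.
#' @param fov_half Field-of-view half-widths (lateral, elevational) in mm.
#'   Default `c(7.5, 7.5)` (15 mm lateral field).
#' @param kinds Which scatterer kinds contribute; default all.
#' @param frame_time Timestamp stamped on the output volume.
#' @return An [ulm_volume()].
#' @export
render_bmode <- function(scene, probe, grid, psf, noise_sigma = 0,
                         fov_half = c(7.5, 7.5),
                         kinds = c("speckle", "landmark", "lobe", "bubble"),
                         frame_time = scene$time) {
  tab <- scene_scatterers(scene)
  tab <- tab[tab$kind %in% kinds, , drop = FALSE]
  pos <- world_to_probe(cbind(tab$x_mm, tab$y_mm, tab$z_mm), probe)
  render_points(pos, tab$amplitude, grid, psf, noise_sigma, fov_half,
                frame_time = frame_time)
}

#' Render a contrast (CEUS) volume of a scene
#'
#' As [render_bmode()] but keeping only microbubble scatterers: tissue is
#' assumed perfectly suppressed by the amplitude-modulation scheme, except
#' for an optional residual leakage fraction that re-admits tissue
#' scatterers (e.g. a strongly reflecting phantom wall entering the view).
#'
#' @inheritParams render_bmode
#' @param leakage Fraction of non-bubble amplitude that leaks through tissue
#'   suppression. Default 0.
#' @return An [ulm_volume()].
#' @export
render_contrast <- function(scene, probe, grid, psf, noise_sigma = 0,
                            fov_half = c(7.5, 7.5), leakage = 0,
                            frame_time = scene$time) {
  tab <- scene_scatterers(scene)
  amp <- ifelse(tab$kind == "bubble", tab$amplitude, leakage * tab$amplitude)
  keep <- amp > 0
  pos <- world_to_probe(cbind(tab$x_mm, tab$y_mm, tab$z_mm)[keep, , drop = FALSE],
                        probe)
  render_points(pos, amp[keep], grid, psf, noise_sigma, fov_half,
                frame_time = frame_time)
}

#' Acquire a uniformly timed volume sequence
#'
#' Frames are emitted at exactly `1 / volume_rate` spacing regardless of any
#' downstream processing (the asynchronous-acquisition guarantee). The probe
#' pose for each frame is read from `pose_source` at the frame time, which
#' lets a closed-loop controller move the probe mid-sequence.
#'
#' @param scene A [phantom_scene()].
#' @param profile Stage [motion_profile()] or `NULL`.
#' @param probe A [probe_model()]; its position is overridden per frame by
#'   `pose_source` when supplied.
#' @param grid A [volume_grid()] in the probe frame.
#' @param psf A [psf_model()].
#' @param volume_rate Volumes per second. Default 85.
#' @param duration Sequence length (s); `floor(duration * volume_rate)`
#'   frames are produced.
#' @param pose_source Function `f(t)` returning the probe-frame offset (mm
#'   3-vector) at time `t`, or `NULL` for a static probe.
#' @param render One of `"bmode"`, `"contrast"`.
#' @param ... Passed to the renderer.
#' @return List of [ulm_volume()] frames with uniform timestamps.
#' @export
acquire_sequence <- function(scene, profile, probe, grid, psf,
                             volume_rate = 85, duration = 1,
                             pose_source = NULL, render = c("bmode", "contrast"),
                             ...) {
  render <- match.arg(render)
  stopifnot(volume_rate > 0, duration >= 0)
  n <- floor(duration * volume_rate)
  fun <- if (render == "bmode") render_bmode else render_contrast
  lapply(seq_len(n), function(k) {
    t <- (k - 1) / volume_rate
    pr <- probe
    if (!is.null(pose_source)) pr$position <- pose_source(t)
    sc <- scene_at_time(scene, profile, t)
    fun(sc, pr, grid, psf, frame_time = t, ...)
  })
}

#' Toy delay-and-sum round trip for point targets
#'
#' Simulates each array element's received echo from a small set of point
#' targets under a non-steered plane-wave transmit (transmit delay `z / c`,
#' receive delay `|target - element| / c`), with a Gaussian-enveloped
#' carrier, then beamforms the analytic signal onto the grid by delay and
#' sum. Each target produces an envelope maximum within one voxel of its
#' true position.
#'
#' @param targets Matrix (n x 3) of target positions (mm), `n <= 10`; all
#'   depths must be positive (in front of the array).
#' @param probe A [probe_model()].
#' @param grid A [volume_grid()] (at most 64^3 voxels).
#' @param pulse_cycles Carrier cycles inside one envelope sigma. Default 1.5.
#' @return An [ulm_volume()] of envelope magnitude.
#' @export
das_point_roundtrip <- function(targets, probe, grid, pulse_cycles = 1.5) {
  targets <- rbind(targets)
  if (nrow(targets) > 10) stop("at most 10 point targets")
  if (any(targets[, 3] <= 0)) stop("targets must be in front of the array (z > 0)")
  if (prod(grid$shape) > 64^3) stop("grid too large for the toy DAS model")
  ex <- seq(-probe$aperture[1] / 2, probe$aperture[1] / 2,
            length.out = probe$n_elements[1])
  ey <- seq(-probe$aperture[2] / 2, probe$aperture[2] / 2,
            length.out = probe$n_elements[2])
  elems <- as.matrix(expand.grid(x = ex, y = ey))
  elems <- cbind(elems, 0)
  c_mm_s <- probe$sound_speed * 1e3          # mm/s
  f0 <- probe$center_frequency * 1e6         # Hz
  sigma_t <- pulse_cycles / f0
  data <- cpp_das(grid$shape, grid$origin, grid$pitch, elems, targets,
                  c_mm_s, f0, sigma_t)
  ulm_volume(array(data, dim = grid$shape), origin = grid$origin,
             pitch = grid$pitch, frame_time = grid$frame_time)
}
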