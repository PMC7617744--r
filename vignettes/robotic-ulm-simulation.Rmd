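---
title: "Simulating robot-assisted 4D ultrasound tracking and 3D ULM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating robot-assisted 4D ultrasound tracking and 3D ULM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulmtrack)
```

## The problem

Ultrasound localisation microscopy (ULM) builds super-resolved vascular maps
by localising sparse microbubble echoes to a small fraction of the imaging
wavelength and accumulating those localisations over thousands of frames.
The accumulation assumes the vasculature stays put. Respiratory organ motion
of up to ~20 mm breaks that assumption twice over: the target drifts out of
the probe's small field of view (a matrix-array footprint is only about
10 mm on a side), and image registration cannot recover signal that was
never recorded. One remedy is mechanical: mount the probe on a robot arm,
detect the target's translation in the live volumetric image stream, and
servo the probe so the target stays centred; the remaining (much smaller)
residual motion is then corrected in software during ULM post-processing.

`ulmtrack` is a desk-scale simulator of that entire chain. It contains no
hardware drivers and no radio-frequency physics; every quantity a bench
experiment would measure — closed-loop residual motion versus target speed,
motion-corrected contrast accumulation, super-resolution density and speed
maps, Fourier shell correlation (FSC) resolution — is instead measured on a
synthetic moving phantom with known ground truth.

## The synthetic scene and what it emulates

`phantom_scene()` builds a wall-less crossed-microchannel flow phantom in
the probe frame (x lateral, y elevational, z depth, voxel-centre
convention):

* **Channels.** Two straight cylindrical channels of 200 µm lumen diameter
  (a 180 µm template wire plus two 10 µm conformal coatings) crossing at
  30° at 20 mm depth. Neither the crossing angle nor the depth of the real
  device is published, so both are configuration parameters; the defaults
  were chosen once as a plausible bench geometry and left alone.
* **Flow.** Microbubbles advect along their channel with a parabolic
  (Poiseuille) profile, axial speed `2 * mean * (1 - (r/R)^2)`. The mean
  in-channel speed is not derivable from the published pump rate alone, so
  it is a parameter with default 1 mm/s — the order of magnitude of
  Q/A for about 1.5 µL/min through a 200 µm channel. Bubbles leaving a
  channel recycle at the inlet with a freshly drawn radial offset; the
  draw is a pure function of bubble identity and lap count, so scene
  evaluation is deterministic in time and bubble count is conserved.
* **Landmark.** A 1 mm bright ball (sampled by ~30 surface and centre
  scatterers so its rendered image has a symmetric centroid) with two
  small lobe clusters flanking it, standing in for the printed support
  structure whose exact shape is not published.
* **Tissue.** Diffuse speckle scatterers with Rayleigh-distributed
  amplitudes, uniformly placed in a block around the channels.

Stage motion is a sequence of trapezoidal displacement segments
(`trap_segment()`, `build_protocol()`): constant acceleration of 3 mm/s²,
an optional cruise, constant deceleration; legs span 20 mm; the two bench
protocols are a mixed 4 / 2 mm/s alternation and single-speed sweeps at
1–5 mm/s. Speeds above 5.2 mm/s are rejected — two stacked stages, each
capped at 2.6 mm/s, add their velocities. The motion axis is a unit vector
in the probe frame, so the lateral, elevational and diagonal ("arbitrary",
default 45°) directions are literally the same protocol rotated about
depth; a dwell of 1 s separates legs (not published; fixed once).

## The image formation model and what it leaves out

`render_bmode()` / `render_contrast()` splat each scatterer as an
anisotropic Gaussian blob with the point-spread function's full widths at
half maximum, sum the blobs, and add Gaussian noise. Defaults follow a
diffraction heuristic at the 20 mm working depth: lateral and elevational
FWHM `wavelength * depth / aperture`, axial FWHM two wavelengths
(~0.4 mm at 7.8 MHz, 1540 m/s). Outside the configured field of view
(half-width 7.5 mm, i.e. a 15 mm lateral field) amplitudes roll off under a
Gaussian directivity taper with σ = 0.4 mm, so a target 3 FWHM beyond the
edge contributes less than 10⁻³ of its in-view peak — this is what makes
"the landmark left the field of view" a simulable event. Contrast volumes
keep only bubbles, with an optional leakage fraction re-admitting tissue
(e.g. a bright phantom wall entering the view). Optional side-lobe replicas
(parallel copies at 1.5 mm, amplitude 0.1) are off by default.

This image-domain surrogate deliberately omits: RF sampling and
beamforming, amplitude-modulation pulse sequencing, nonlinear bubble
oscillation, attenuation, and spatial variation of the PSF shape across
the view (captured only as the amplitude taper). Consequences for
interpretation: registration in this simulator sees speckle that
decorrelates only through motion, never through PSF change, so simulated
registration latencies must be imposed rather than emerge; and localisation
precision here bounds what matched-filter localisation could achieve, not
what a specific scanner achieves. A toy `das_point_roundtrip()` (per-element
delays from a non-steered plane-wave transmit, delay-and-sum of an analytic
pulse) is included to verify the geometric delay arithmetic on point
targets, not to model image texture.

## The asynchronous servo loop

`run_async_loop()` reproduces the acquisition/processing/robot timeline as
a sequential event simulation:

* Acquisition emits frames at exactly 85 Hz whatever the processing does —
  the timestamps are uniform by construction, mirroring the asynchronous
  design that decouples frame rate from control rate.
* Each processing cycle grabs the **latest** frame, beamforms it on the
  online grid (a ~12.5 mm crop at 0.4 mm pitch, about 3 × 10⁴ voxels,
  centred on the landmark), estimates the target's **translation** relative
  to the **first** frame (3 degrees of freedom; rotations are ignored
  online because a rotated target is still in view), and commands the robot
  to the absolute pose that cancels it. The command is withheld if the pose
  leaves the safety workspace (±50 mm lateral/elevational, ±5 mm depth,
  closed intervals). Depth commands are zeroed by default: a probe must
  never chase axial motion into the patient.
* Stage latencies per cycle: beamforming 0.04 s; registration drawn
  uniformly from 0.04–0.3 s (the published range; the distribution within
  it is unknown, and a uniform draw is the least-informative choice);
  robot stage 0.03 s command transmission **plus** the trapezoidal
  execution time of the move (250 mm/s² acceleration to at most 50 mm/s —
  moves under 10 mm never cruise, so the probe only accelerates and
  decelerates). The next cycle starts when the robot finishes: the loop is
  sequential, so no command queue is needed.
* The landmark's displacement relative to the first frame is logged for
  every acquired frame (lateral and elevational components).

Two detection modes exist: `"image"` renders the online crop and runs the
translation registration (regular-step gradient descent over a 3-level
pyramid with an exhaustive integer-voxel search at the coarsest level);
`"ideal"` short-circuits to the geometric displacement plus Gaussian noise.
They agree closely in the closed loop (tested), and `"ideal"` is used where
many runs are needed quickly.

Residual motion is evaluated as on the bench (`detect_onset()`,
`residual_stats()`): motion onset is the first frame whose displacement
magnitude exceeds 0.1 mm, the end is the last, and the mean and standard
deviation are taken over the in-motion frames only.
`evaluate_residual_series()` provides the image-domain route: re-render at
0.1 mm pitch and localise the landmark by weighted centroiding
(background-floor subtraction, then an intensity-weighted mean over a
2.6 mm region of interest that follows the landmark between frames — a
fixed large window would be biased toward the surrounding speckle).

A note on what the latency model implies: with the registration time drawn
uniformly over its full published range, the simulated mean in-motion
residual at the 5 mm/s protocol comes out higher than a system whose
registration usually converges near the fast end of that range. The
uniform draw is the honest choice given only a range, and no generator or
latency parameter here was adjusted to move that number; the simulator's
residuals should be read as an upper-bound regime of the published
behaviour. The qualitative properties — residual growing monotonically
(and roughly linearly) with target speed, the majority of in-motion frames
within 2 mm at top speed, the landmark held in view where a fixed probe
loses it — are reproduced and tested.

## Offline reconstruction

`estimate_rigid_lm()` performs 6-DoF rigid registration by minimising the
sum of squared intensity differences with a Levenberg–Marquardt solver:
analytic Jacobian from trilinearly sampled image gradients (computed on
volumes smoothed by a 0.5-voxel Gaussian to stabilise speckle
derivatives), multiplicative damping adapted on each step, convergence
when the parameter step falls below 10⁻⁴ (mm, with rotations scaled by the
lever arm to the rotation centre) or the relative cost decrease below
10⁻⁸, at most 200 iterations. Rotations are extrinsic XYZ in degrees about
the volume centroid. Because the SSD basin on speckle is only about one
PSF width wide, the solver runs coarse-to-fine over a pyramid, and for
large motions the documented recipe is a translation-pyramid estimate
first, then LM refinement; in frame sequences the previous frame's result
warm-starts the next, which measurably cuts iterations. Each frame's
contrast volume is then mapped to reference coordinates
(`resample_volume()` for per-frame correction; `lagrangian_accumulate()`
scatters frame values to reference voxels with trilinear weights when a
single accumulated volume is wanted).

The ULM chain (`suppress_background()` → `estimate_psf()` → `ncc_map()` →
`localise()` → `link_tracks()` → `persistence_filter()` →
`accumulate_maps()` → `smooth_maps()`) follows the published recipe with
these fixed numerical choices where the text leaves room:

* Adaptive threshold: a voxel survives only if it **strictly** exceeds
  both the Gaussian-weighted mean of its 5³ neighbourhood (centre
  excluded) and the empirical noise floor (default 3× a background
  standard-deviation estimate); ties remove the voxel, so a uniform volume
  at the floor value is fully zeroed.
* PSF template: peak-normalised single-bubble patches aligned by centre of
  mass and averaged (five patches on the bench; at least two here, or an
  explicit single-patch flag). The simulator can also render the template
  directly from its own PSF model.
* Localisation: strict 26-neighbourhood maxima of the normalised
  cross-correlation map above 0.5; the 3³ neighbourhood of each peak is
  interpolated 5× per axis with natural cubic splines and the refined
  maximum taken; peaks within one voxel merge, keeping the higher score.
* Linking: a gated, globally optimal per-frame-pair assignment (Hungarian
  algorithm) on predicted-position distance, constant-velocity prediction
  once a track has two points, gate `max_speed / volume_rate` with
  defaults 10 mm/s and no gap bridging. This is a documented stand-in for
  the feature-motion-model tracker used on the bench, whose internals are
  not published.
* Maps: tracks rasterised as polylines onto a 0.02 mm grid; the density
  map counts **distinct trajectories** per voxel (once per track, however
  long it lingers; per-visit counting is available behind a flag), the
  speed map averages the passing tracks' local speeds. Display smoothing:
  40 µm FWHM Gaussian for density (mass-conserving), 60 µm-diameter
  spherical mean filter for speed restricted to perfused voxels.

## FSC resolution

`split_odd_even()` halves the track set by index parity and accumulates two
independent density maps; `fsc_curve()` correlates their spectra over
one-bin-wide frequency shells (voxels round to the nearest integer shell
radius; anisotropic grids are handled in physical frequency); the
resolution is the reciprocal of the first frequency where the correlation
falls below the 1/2-bit information threshold
`(0.2071 + 1.9102/sqrt(n)) / (1.2071 + 0.9102/sqrt(n))`, linearly
interpolated between bracketing shells, with the DC shell excluded. When
the curve never crosses, the map is band-limited by its own grid and the
function reports the grid-Nyquist sentinel (40 µm at 0.02 mm pitch) rather
than an extrapolated number — resolutions finer than Nyquist on these maps
would require zero-padding or a finer accumulation grid, and the search is
deliberately bounded instead.

## Problem sizes

The package's own test and demonstration sizes, chosen so the full chain
runs in minutes on one CPU: closed-loop runs use one 20 mm round trip per
speed (the bench used five) with a few hundred speckle scatterers and
10–20 concurrent bubbles; offline reconstructions use 40–120 frames on a
~6 mm, 0.1 mm-pitch volume with the super-resolution maps on a thin
0.02 mm slab containing the channels; registration benchmarks use 64³
volumes at 0.1 mm pitch. All randomness flows from a single user seed per
run; scene construction and bubble recycling use an isolated stream, so a
run is reproducible bit for bit for its deterministic stages.

## Known limitations

Simulated registration never fails for image-quality reasons, so the
latency ranges are imposed, not emergent; the PSF is spatially invariant;
contrast suppression is perfect unless leakage is configured; no elastic
deformation exists (the phantom is rigid, as is the bench phantom); and
out-of-plane probe rotation is not modelled (the pose has one rotational
degree of freedom, about depth). Conclusions drawn from passing tests are
therefore about the control timeline, the reconstruction algebra and the
statistical machinery — not about acoustic image quality.

## A short worked run

```{r example, eval = FALSE}
scene <- phantom_scene(n_speckle = 800, n_bubbles = 10, seed = 1)
profile <- build_protocol("single_speed", speed = 5, range = 20,
                          n_round_trips = 1)
log <- run_async_loop(scene, profile, detection = "image", seed = 1)
series <- detect_onset(series_from_log(log), threshold = 0.1)
residual_stats(series)[c("mean_mm", "sd_mm")]

cfg <- default_config(speed = 4, detection = "ideal", seed = 5)
rec <- cmd_reconstruct(cfg, n_frames = 40, frame_stride = 6)
rec$fsc$resolution
```
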