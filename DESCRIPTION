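Package: ulmtrack
Title: Simulation of Robot-Assisted 4D Ultrasound Target Tracking and 3D
    Ultrasound Localisation Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator and reconstruction pipeline for
    robot-assisted volumetric (4D) ultrasound imaging of moving targets.
    Generates a crossed-microchannel flow phantom with a landmark scatterer,
    moves it with trapezoidal stage kinematics, images it with a virtual
    matrix-array probe, and closes the loop with an asynchronous
    acquisition/registration/robot-command servo that holds the target in
    the field of view. Offline tools provide translation-only and 6-DoF
    rigid registration (sum-of-squared-differences cost, Levenberg-Marquardt
    solver), Lagrangian motion-corrected accumulation, a full ultrasound
    localisation microscopy chain (adaptive background suppression, PSF
    estimation, normalised cross-correlation localisation with sub-voxel
    interpolation, gated optimal-assignment tracking, persistence filtering,
    super-resolution density and speed maps), residual-motion evaluation,
    and Fourier shell correlation resolution analysis at the 1/2-bit
    threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
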