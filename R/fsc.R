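#' Split tracks into odd/even halves and accumulate half-maps
#'
#' Partitions the trajectories by index parity and accumulates two density
#' maps independently on the same grid — the standard half-data split for
#' Fourier shell correlation.
#'
#' @param tracks Track table ([link_tracks()] format) with >= 2 tracks.
#' @param grid A [volume_grid()].
#' @return List with `odd` and `even` `ulm_maps`.
#' @export
split_odd_even <- function(tracks, grid) {
  ids <- unique(tracks$track_id)
  if (length(ids) < 2) stop("at least two tracks are required for a half split")
  odd_ids <- ids[seq_along(ids) %% 2 == 1]
  even_ids <- ids[seq_along(ids) %% 2 == 0]
  list(odd = accumulate_maps(tracks[tracks$track_id %in% odd_ids, ], grid),
       even = accumulate_maps(tracks[tracks$track_id %in% even_ids, ], grid))
}

#' Fourier shell correlation between two volumes
#'
#' Correlates the two volumes' spectra over concentric frequency shells of
#' one frequency-bin width (voxels round to the nearest integer radius):
#' the real part of the normalised cross-spectral sum per shell. Shells
#' with zero energy in either volume are flagged undefined.
#'
#' @param vol_a,vol_b [ulm_volume()]s on the same grid.
#' @return An object of class `fsc_curve`: data frame with
#'   `shell` (bin radius), `freq_cyc_per_mm`, `correlation`, `n_voxels`,
#'   `threshold` (1/2-bit), `defined`.
#' @export
fsc_curve <- function(vol_a, vol_b) {
  stopifnot(inherits(vol_a, "ulm_volume"), inherits(vol_b, "ulm_volume"))
  if (!all(dim(vol_a$data) == dim(vol_b$data)))
    stop("half-maps must share one grid")
  d <- dim(vol_a$data)
  A <- stats::fft(vol_a$data)
  B <- stats::fft(vol_b$data)
  # integer shell radius per voxel (frequency bins, anisotropy-corrected to
  # the first axis' bin size)
  fbin <- 1 / (d * vol_a$pitch)         # cycles/mm per bin, per axis
  fidx <- lapply(1:3, function(ax) {
    k <- seq_len(d[ax]) - 1
    pmin(k, d[ax] - k) * fbin[ax]
  })
  fr <- sqrt(outer(outer(fidx[[1]]^2, fidx[[2]]^2, "+"), fidx[[3]]^2, "+"))
  shell <- round(fr / fbin[1])
  nmax <- floor(min(d) / 2)
  shell[shell > nmax] <- -1L
  sh <- as.integer(shell)
  num <- Re(rowsum_complex(A * Conj(B), sh))
  ea <- rowsum_dbl(abs(A)^2, sh)
  eb <- rowsum_dbl(abs(B)^2, sh)
  shells <- sort(unique(sh[sh >= 0]))
  n_vox <- as.numeric(table(factor(sh[sh >= 0], levels = shells)))
  idx <- match(shells, sort(unique(sh)))
  den <- sqrt(ea[idx] * eb[idx])
  defined <- den > 0
  corr <- ifelse(defined, num[idx] / pmax(den, 1e-300), NA_real_)
  out <- data.frame(shell = shells,
                    freq_cyc_per_mm = shells * fbin[1],
                    correlation = corr,
                    n_voxels = n_vox,
                    threshold = halfbit_threshold(n_vox),
                    defined = defined)
  class(out) <- c("fsc_curve", "data.frame")
  out
}

rowsum_complex <- function(x, g) {
  re <- rowsum(as.numeric(Re(x)), g)
  im <- rowsum(as.numeric(Im(x)), g)
  complex(real = re, imaginary = im)
}

rowsum_dbl <- function(x, g) as.numeric(rowsum(as.numeric(x), g))

#' 1/2-bit information threshold
#'
#' The per-shell significance threshold corresponding to half a bit of
#' information (van Heel & Schatz):
#' `T(n) = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))`,
#' decreasing in the shell voxel count `n` towards 0.1716.
#'
#' @param n_voxels Voxel counts per shell (>= 1).
#' @return Threshold values, one per shell.
#' @export
halfbit_threshold <- function(n_voxels) {
  stopifnot(all(n_voxels >= 1))
  s <- sqrt(n_voxels)
  (0.2071 + 1.9102 / s) / (1.2071 + 0.9102 / s)
}

#' FSC resolution at the 1/2-bit threshold
#'
#' The resolution is the reciprocal of the first frequency at which the
#' correlation falls below the per-shell 1/2-bit threshold, linearly
#' interpolated between the bracketing shells. The DC shell is excluded
#' from the search; when the curve never crosses, the map is band-limited
#' by its own grid and the Nyquist-limited sentinel is returned.
#'
#' @param curve An `fsc_curve` from [fsc_curve()].
#' @return List with `resolution_um`, `crossing_freq_cyc_per_mm`, and
#'   `crossed` (FALSE means better than the grid Nyquist).
#' @export
fsc_resolution <- function(curve) {
  stopifnot(inherits(curve, "fsc_curve"))
  cv <- curve[curve$shell > 0 & curve$defined, , drop = FALSE]
  if (nrow(cv) < 3) stop("the curve must be defined on at least 3 shells")
  diffv <- cv$correlation - cv$threshold
  below <- which(diffv < 0)
  if (!length(below)) {
    nyq <- max(cv$freq_cyc_per_mm)
    return(list(resolution_um = 1 / nyq * 1000,
                crossing_freq_cyc_per_mm = nyq, crossed = FALSE))
  }
  k <- below[1]
  if (k == 1) {
    f <- cv$freq_cyc_per_mm[1]
  } else {
    f0 <- cv$freq_cyc_per_mm[k - 1]; f1 <- cv$freq_cyc_per_mm[k]
    d0 <- diffv[k - 1]; d1 <- diffv[k]
    f <- f0 + d0 / (d0 - d1) * (f1 - f0)
  }
  list(resolution_um = 1 / f * 1000, crossing_freq_cyc_per_mm = f,
       crossed = TRUE)
}

#' Write an FSC curve as CSV
#' @param curve An `fsc_curve`.
#' @param path Output path.
#' @return The data frame, invisibly.
#' @export
write_fsc_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(curve)
}
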