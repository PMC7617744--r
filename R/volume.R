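#' 3D image volume with physical geometry
#'
#' A dense 3D intensity grid together with its physical placement: `origin`
#' is the position (mm) of the centre of voxel `[1, 1, 1]`, `pitch` the
#' voxel size per axis (mm), and `frame_time` the acquisition timestamp (s).
#' Axes follow the probe convention x = lateral, y = elevational, z = depth.
#'
#' @param data 3D numeric array (x, y, z).
#' @param origin mm 3-vector, voxel-centre convention.
#' @param pitch mm per axis; scalar recycled to 3.
#' @param frame_time Timestamp (s). Default 0.
#' @return An object of class `ulm_volume`.
#' @export
ulm_volume <- function(data, origin = c(0, 0, 0), pitch = 1, frame_time = 0) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  pitch <- rep(as.numeric(pitch), length.out = 3L)
  if (any(pitch <= 0)) stop("`pitch` must be positive on every axis")
  structure(list(data = data, origin = as.numeric(origin), pitch = pitch,
                 frame_time = frame_time),
            class = "ulm_volume")
}

#' Regular voxel grid specification
#'
#' @param origin mm 3-vector (centre of the first voxel).
#' @param pitch mm per axis (scalar recycled).
#' @param shape Integer voxels per axis.
#' @param frame_time Timestamp (s).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(origin, pitch, shape, frame_time = 0) {
  pitch <- rep(as.numeric(pitch), length.out = 3L)
  shape <- rep(as.integer(shape), length.out = 3L)
  if (any(pitch <= 0)) stop("`pitch` must be positive on every axis")
  if (any(shape < 1)) stop("`shape` must be at least 1 voxel per axis")
  structure(list(origin = as.numeric(origin), pitch = pitch, shape = shape,
                 frame_time = frame_time),
            class = "volume_grid")
}

#' Grid centred on a point
#'
#' Convenience constructor: an isotropic grid of physical size `size` (mm)
#' centred at `center`.
#'
#' @param center mm 3-vector.
#' @param size Physical extent per axis (mm; scalar recycled).
#' @param pitch Voxel pitch (mm; scalar recycled).
#' @return A [volume_grid()].
#' @export
centered_grid <- function(center, size, pitch) {
  pitch <- rep(pitch, length.out = 3L)
  size <- rep(size, length.out = 3L)
  shape <- pmax(1L, as.integer(round(size / pitch)))
  origin <- center - (shape - 1) / 2 * pitch
  volume_grid(origin, pitch, shape)
}

#' @export
print.ulm_volume <- function(x, ...) {
  cat(sprintf("<ulm_volume> %s voxels, pitch %s mm, origin (%s) mm, t = %.4f s\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$pitch, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", "), x$frame_time))
  invisible(x)
}

vol_axis <- function(vol, i) {
  vol$origin[i] + (seq_len(dim(vol$data)[i]) - 1) * vol$pitch[i]
}

# physical mm -> 0-based fractional voxel coordinates
mm_to_voxel <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$pitch, "/")
}

voxel_to_mm <- function(vol, idx0) {
  sweep(sweep(idx0, 2, vol$pitch, "*"), 2, vol$origin, "+")
}

grid_points <- function(vol) {
  d <- dim(vol$data)
  as.matrix(expand.grid(x = vol_axis(vol, 1), y = vol_axis(vol, 2),
                        z = vol_axis(vol, 3)))
}

#' Crop a physical sub-volume
#'
#' Extracts the sub-volume of physical size `size` (mm per axis) centred at
#' `center`, snapped to the parent voxel grid. The voxel count per axis is
#' `round(size / pitch)`, so a 12.5 mm cube at 0.4 mm pitch has 31^3 = 29791
#' voxels.
#'
#' @param volume An [ulm_volume()].
#' @param center mm 3-vector, inside the volume.
#' @param size mm per axis (scalar recycled).
#' @return The cropped `ulm_volume` (geometry preserved).
#' @export
crop_volume <- function(volume, center, size) {
  stopifnot(inherits(volume, "ulm_volume"))
  size <- rep(size, length.out = 3L)
  d <- dim(volume$data)
  n <- pmax(1L, as.integer(round(size / volume$pitch)))
  ctr_idx <- round((center - volume$origin) / volume$pitch)  # 0-based
  first <- as.integer(ctr_idx - (n - 1) %/% 2)               # 0-based
  last <- first + n - 1L
  if (any(first < 0L) || any(last > d - 1L))
    stop("crop exceeds the volume extent")
  out <- volume$data[first[1]:last[1] + 1L, first[2]:last[2] + 1L,
                     first[3]:last[3] + 1L, drop = FALSE]
  ulm_volume(out, origin = volume$origin + first * volume$pitch,
             pitch = volume$pitch, frame_time = volume$frame_time)
}

#' Write / read a volume as NIfTI
#'
#' The voxel pitch is stored in the NIfTI header (`pixdim`); the physical
#' origin and frame time are carried in a JSON sidecar next to the file.
#'
#' @param volume An [ulm_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (for the writer); an `ulm_volume` (reader).
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$data, pixdim = volume$pitch)
  RNifti::writeNifti(img, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(origin_mm = volume$origin, pitch_mm = volume$pitch,
                            frame_time_s = volume$frame_time),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    ulm_volume(array(as.numeric(img), dim = dim(img)),
               origin = meta$origin_mm, pitch = meta$pitch_mm,
               frame_time = meta$frame_time_s)
  } else {
    ulm_volume(array(as.numeric(img), dim = dim(img)),
               pitch = RNifti::pixdim(img)[1:3])
  }
}

#' Write a volume as multi-page TIFF
#'
#' Depth slices become TIFF pages. Intensities are rescaled to `[0, 1]`
#' (the range the TIFF writer stores); the scale and offset, together with
#' the grid geometry, go to a JSON sidecar (TIFF has no calibrated 3D
#' header).
#'
#' @inheritParams write_volume_nifti
#' @export
write_volume_tiff <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF output")
  lo <- min(volume$data)
  hi <- max(volume$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(volume$data)[3]),
                  function(k) t((volume$data[, , k] - lo) / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(origin_mm = volume$origin, pitch_mm = volume$pitch,
                            frame_time_s = volume$frame_time,
                            intensity_offset = lo, intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
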