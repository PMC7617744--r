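#' Rigid transform (3 translations + 3 rotations)
#'
#' Parameterises the rigid motion of the imaged object between a reference
#' volume and a moving volume: the object at reference position `x` appears
#' in the moving volume at `R (x - center) + center + translation`, with `R`
#' composed from extrinsic rotations about the fixed X, Y then Z axes
#' (angles in degrees). `translation` is therefore the physical displacement
#' the tracker must cancel.
#'
#' @param translation mm 3-vector.
#' @param rotation deg 3-vector, extrinsic XYZ order.
#' @param center Rotation centre (mm 3-vector).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3, length(center) == 3,
            all(is.finite(c(translation, rotation, center))))
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix <- function(rot_deg) {
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#' @param transform A [rigid_transform()].
#' @param pts n x 3 matrix of mm positions.
#' @return n x 3 matrix of transformed positions.
#' @export
transform_points <- function(transform, pts) {
  R <- rotation_matrix(transform$rotation)
  ctr <- transform$center
  out <- sweep(pts, 2, ctr, "-") %*% t(R)
  sweep(out, 2, ctr + transform$translation, "+")
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform` (same rotation centre).
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  # inverse: x = R^T (y - c - t) + c = R^T(y - c) + c + [R^T(-t) ... ]
  Rt <- t(R)
  rot_inv <- rotmat_to_xyz_deg(Rt)
  t_inv <- as.numeric(Rt %*% (-transform$translation))
  rigid_transform(t_inv, rot_inv, transform$center)
}

# recover extrinsic XYZ angles (deg) from a rotation matrix R = Rz Ry Rx
rotmat_to_xyz_deg <- function(R) {
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Compose two rigid transforms
#' @param a,b [rigid_transform()]s sharing a rotation centre convention;
#'   the result applies `b` first, then `a`.
#' @return A `rigid_transform` with `a`'s centre.
#' @export
compose_transforms <- function(a, b) {
  R <- rotation_matrix(a$rotation) %*% rotation_matrix(b$rotation)
  rot <- rotmat_to_xyz_deg(R)
  ca <- a$center
  # fix the translation so that the composite acts like a after b
  o <- transform_points(a, transform_points(b, rbind(c(0, 0, 0))))
  base <- transform_points(rigid_transform(c(0, 0, 0), rot, ca), rbind(c(0, 0, 0)))
  rigid_transform(as.numeric(o - base), rot, ca)
}

#' Registration result
#' @param transform Estimated [rigid_transform()].
#' @param final_cost Final sum-of-squared-differences cost.
#' @param n_iterations Iterations used.
#' @param converged Convergence flag.
#' @return An object of class `registration_result`.
#' @export
registration_result <- function(transform, final_cost, n_iterations, converged) {
  structure(list(transform = transform, final_cost = final_cost,
                 n_iterations = n_iterations, converged = converged),
            class = "registration_result")
}

# sample a volume (and optionally its gradient volumes) at mm positions
sample_volume <- function(vol, pts_mm, fill = NA_real_) {
  v <- mm_to_voxel(vol, pts_mm)
  cpp_trilinear(as.numeric(vol$data), dim(vol$data), v, fill)
}

gradient_volumes <- function(vol, smooth_sigma_vox = 0.5) {
  d <- vol$data
  if (smooth_sigma_vox > 0) d <- gaussian_smooth3(d, rep(smooth_sigma_vox, 3))
  dims <- dim(d)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- dims[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * vol$pitch[ax]
    gi <- switch(ax,
                 (d[ip, , , drop = FALSE] - d[im, , , drop = FALSE]),
                 (d[, ip, , drop = FALSE] - d[, im, , drop = FALSE]),
                 (d[, , ip, drop = FALSE] - d[, , im, drop = FALSE]))
    shape_denom <- switch(ax, denom, rep(denom, each = dims[1]),
                          rep(denom, each = dims[1] * dims[2]))
    g[[ax]] <- ulm_volume(gi / array(shape_denom, dims), vol$origin, vol$pitch,
                          vol$frame_time)
  }
  g
}

# separable Gaussian smoothing of a 3D array, sigma per axis in voxels
gaussian_smooth3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(m)
  # replicate-pad then convolve columns
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  b <- array(out, dim(a))
  aperm(b, order(perm))
}

ssd_cost <- function(ref, mov, tf) {
  pts <- transform_points(tf, grid_points(ref))
  s <- sample_volume(mov, pts)
  ok <- s$valid
  if (!any(ok)) return(Inf)
  sum((s$values[ok] - as.numeric(ref$data)[ok])^2) / sum(ok)
}

downsample2 <- function(vol) {
  d <- dim(vol$data)
  n2 <- pmax(1L, d %/% 2L)
  idx <- lapply(1:3, function(ax) 2L * seq_len(n2[ax]) - 1L)
  a <- vol$data
  sm <- gaussian_smooth3(a, rep(0.85, 3))
  out <- sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  ulm_volume(out, origin = vol$origin, pitch = vol$pitch * 2,
             frame_time = vol$frame_time)
}

#' Translation-only registration (regular-step gradient descent, pyramid)
#'
#' Estimates the 3-DoF translation minimising the sum of squared intensity
#' differences between `reference` and `moving`, coarse-to-fine over a
#' Gaussian pyramid (2x downsampling per level). This is the fast online
#' estimator used by the servo loop.
#'
#' @param reference,moving [ulm_volume()]s on the same grid geometry.
#' @param n_pyramid_levels Pyramid depth. Default 3.
#' @param init Initial translation (mm 3-vector). Default zeros.
#' @param max_iter Iterations per level. Default 60.
#' @param min_step Step-length convergence threshold, as a fraction of the
#'   finest voxel pitch. Default 0.01.
#' @param coarse_search Bracket the shift by an exhaustive integer-voxel
#'   search at the coarsest level before descending. Default TRUE.
#' @return A [registration_result()] whose transform has zero rotation; the
#'   translation is the physical displacement of the imaged object from
#'   reference to moving.
#' @export
estimate_translation <- function(reference, moving, n_pyramid_levels = 3,
                                 init = c(0, 0, 0), max_iter = 60,
                                 min_step = 0.01, coarse_search = TRUE) {
  stopifnot(inherits(reference, "ulm_volume"), inherits(moving, "ulm_volume"))
  if (stats::sd(reference$data) == 0 || stats::sd(moving$data) == 0)
    return(registration_result(rigid_transform(init), Inf, 0L, FALSE))
  pyr_ref <- list(reference); pyr_mov <- list(moving)
  if (n_pyramid_levels > 1)
    for (l in seq_len(n_pyramid_levels - 1)) {
      pyr_ref[[l + 1]] <- downsample2(pyr_ref[[l]])
      pyr_mov[[l + 1]] <- downsample2(pyr_mov[[l]])
    }
  t_cur <- as.numeric(init)
  iters <- 0L
  # exhaustive integer-voxel search at the coarsest level: gradient descent
  # on speckle SSD only converges within about one correlation length, so
  # large shifts are bracketed by direct search first
  if (coarse_search) {
    top <- pyr_ref[[length(pyr_ref)]]
    topm <- pyr_mov[[length(pyr_mov)]]
    t_cur <- coarse_shift_search(top, topm, t_cur)
  }
  for (l in rev(seq_len(n_pyramid_levels))) {
    ref <- pyr_ref[[l]]; mov <- pyr_mov[[l]]
    grad <- gradient_volumes(mov)
    pts0 <- grid_points(ref)
    refv <- as.numeric(ref$data)
    step <- max(ref$pitch) / 2
    min_step_mm <- min_step * min(reference$pitch)
    cost_at <- function(tr) {
      s <- cpp_trilinear(as.numeric(mov$data), dim(mov$data),
                         mm_to_voxel(mov, sweep(pts0, 2, tr, "+")), NA_real_)
      ok <- s$valid
      if (sum(ok) < 8) return(Inf)
      sum((s$values[ok] - refv[ok])^2) / sum(ok)
    }
    cost <- cost_at(t_cur)
    it <- 0L
    while (it < max_iter && step > min_step_mm) {
      it <- it + 1L
      pts <- sweep(pts0, 2, t_cur, "+")
      vox <- mm_to_voxel(mov, pts)
      s <- cpp_trilinear(as.numeric(mov$data), dim(mov$data), vox, NA_real_)
      ok <- s$valid
      if (sum(ok) < 8) break
      resid <- s$values[ok] - refv[ok]
      g <- vapply(1:3, function(ax) {
        gv <- cpp_trilinear(as.numeric(grad[[ax]]$data), dim(mov$data),
                            vox[ok, , drop = FALSE], 0)$values
        2 * sum(resid * gv) / sum(ok)
      }, 0)
      gn <- sqrt(sum(g^2))
      if (gn == 0) break
      t_new <- t_cur - step * g / gn
      cost_new <- cost_at(t_new)
      if (cost_new < cost) {
        t_cur <- t_new
        cost <- cost_new
      } else {
        step <- step / 2
      }
    }
    iters <- iters + it
  }
  final <- ssd_cost_translation(reference, moving, t_cur)
  registration_result(rigid_transform(t_cur), final, iters,
                      converged = is.finite(final))
}

# best integer-voxel shift (mm) of mov relative to ref by direct SSD search
coarse_shift_search <- function(ref, mov, init) {
  d <- dim(ref$data)
  rmax <- pmax(1L, d %/% 3L)
  init_vox <- round(init / ref$pitch)
  best <- init
  best_cost <- Inf
  rv <- ref$data; mv <- mov$data
  for (sz in -rmax[3]:rmax[3]) for (sy in -rmax[2]:rmax[2])
    for (sx in -rmax[1]:rmax[1]) {
      s <- c(sx, sy, sz) + init_vox
      lo_r <- pmax(1L, 1L - s); hi_r <- pmin(d, d - s)
      if (any(hi_r - lo_r < 3)) next
      lo_m <- lo_r + s; hi_m <- hi_r + s
      if (any(lo_m < 1L) || any(hi_m > d)) next
      a <- rv[lo_r[1]:hi_r[1], lo_r[2]:hi_r[2], lo_r[3]:hi_r[3]]
      b <- mv[lo_m[1]:hi_m[1], lo_m[2]:hi_m[2], lo_m[3]:hi_m[3]]
      cost <- mean((a - b)^2)
      if (cost < best_cost) {
        best_cost <- cost
        best <- s * ref$pitch
      }
    }
  best
}

ssd_cost_translation <- function(ref, mov, tr) {
  s <- cpp_trilinear(as.numeric(mov$data), dim(mov$data),
                     mm_to_voxel(mov, sweep(grid_points(ref), 2, tr, "+")),
                     NA_real_)
  ok <- s$valid
  if (!any(ok)) return(Inf)
  sum((s$values[ok] - as.numeric(ref$data)[ok])^2) / sum(ok)
}

#' 6-DoF rigid registration with Levenberg-Marquardt
#'
#' Minimises the sum of squared intensity differences over translations and
#' extrinsic-XYZ rotations, with an adaptively damped Gauss-Newton
#' (Levenberg-Marquardt) update. Gradients are taken on volumes smoothed by
#' a 0.5-voxel Gaussian to stabilise speckle derivatives. Warm-starting
#' `init` from the previous frame's result speeds up convergence on smooth
#' motion sequences.
#'
#' @param reference,moving [ulm_volume()]s on the same grid.
#' @param init Initial [rigid_transform()]. Defaults to identity about the
#'   volume centroid.
#' @param max_iter Maximum LM iterations. Default 200.
#' @param step_tol Convergence threshold on the parameter step (mm; rotation
#'   steps are scaled by the lever arm). Default 1e-4.
#' @param cost_tol Relative cost-decrease convergence threshold.
#'   Default 1e-8.
#' @param n_pyramid_levels Coarse-to-fine pyramid depth (2x downsampling per
#'   level); the LM basin on speckle is only about one PSF width wide, so
#'   larger motions are captured at the coarse levels. Default 3.
#' @return A [registration_result()].
#' @export
estimate_rigid_lm <- function(reference, moving, init = NULL, max_iter = 200,
                              step_tol = 1e-4, cost_tol = 1e-8,
                              n_pyramid_levels = 3) {
  stopifnot(inherits(reference, "ulm_volume"), inherits(moving, "ulm_volume"))
  d <- dim(reference$data)
  centroid <- reference$origin + (d - 1) / 2 * reference$pitch
  if (is.null(init)) init <- rigid_transform(center = centroid)
  stopifnot(inherits(init, "rigid_transform"),
            all(is.finite(c(init$translation, init$rotation))))
  if (stats::sd(reference$data) == 0 || stats::sd(moving$data) == 0)
    return(registration_result(init, Inf, 0L, FALSE))
  if (n_pyramid_levels > 1) {
    pyr_ref <- list(reference); pyr_mov <- list(moving)
    for (l in seq_len(n_pyramid_levels - 1)) {
      if (any(dim(pyr_ref[[l]]$data) < 12)) break
      pyr_ref[[l + 1]] <- downsample2(pyr_ref[[l]])
      pyr_mov[[l + 1]] <- downsample2(pyr_mov[[l]])
    }
    res <- NULL
    tf <- init
    iters <- 0L
    for (l in rev(seq_along(pyr_ref))) {
      res <- lm_core(pyr_ref[[l]], pyr_mov[[l]], tf, max_iter, step_tol,
                     cost_tol)
      tf <- res$transform
      iters <- iters + res$n_iterations
    }
    res$n_iterations <- iters
    return(res)
  }
  lm_core(reference, moving, init, max_iter, step_tol, cost_tol)
}

lm_core <- function(reference, moving, init, max_iter = 200,
                    step_tol = 1e-4, cost_tol = 1e-8) {
  ctr <- init$center
  lever <- max(sqrt(rowSums(sweep(grid_points(reference), 2, ctr, "-")^2)))
  deg_scale <- lever * pi / 180           # mm of motion per degree at the rim
  grad <- gradient_volumes(moving)
  pts0 <- grid_points(reference)
  refv <- as.numeric(reference$data)
  movv <- as.numeric(moving$data)
  mdim <- dim(moving$data)

  p <- c(init$translation, init$rotation)   # tx ty tz (mm), rx ry rz (deg)
  cost_of <- function(p) {
    tf <- rigid_transform(p[1:3], p[4:6], ctr)
    s <- cpp_trilinear(movv, mdim, mm_to_voxel(moving, transform_points(tf, pts0)),
                       NA_real_)
    ok <- s$valid
    if (sum(ok) < 32) return(list(cost = Inf, ok = ok))
    list(cost = sum((s$values[ok] - refv[ok])^2) / sum(ok), ok = ok,
         resid = s$values[ok] - refv[ok])
  }
  cur <- cost_of(p)
  cost <- cur$cost
  lambda <- 1e-3
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    tf <- rigid_transform(p[1:3], p[4:6], ctr)
    tp <- transform_points(tf, pts0)
    vox <- mm_to_voxel(moving, tp)
    s <- cpp_trilinear(movv, mdim, vox, NA_real_)
    ok <- s$valid
    if (sum(ok) < 32) break
    resid <- s$values[ok] - refv[ok]
    gx <- cpp_trilinear(as.numeric(grad[[1]]$data), mdim, vox[ok, , drop = FALSE], 0)$values
    gy <- cpp_trilinear(as.numeric(grad[[2]]$data), mdim, vox[ok, , drop = FALSE], 0)$values
    gz <- cpp_trilinear(as.numeric(grad[[3]]$data), mdim, vox[ok, , drop = FALSE], 0)$values
    # d(residual)/d(params): translations move sample points directly;
    # rotations move them by dR/dtheta (x - c)
    xc <- sweep(pts0[ok, , drop = FALSE], 2, ctr, "-")
    J <- matrix(0, sum(ok), 6)
    J[, 1] <- gx; J[, 2] <- gy; J[, 3] <- gz
    eps <- 1e-4
    for (k in 1:3) {
      rp <- p[4:6]; rp[k] <- rp[k] + eps
      rm <- p[4:6]; rm[k] <- rm[k] - eps
      dR <- (rotation_matrix(rp) - rotation_matrix(rm)) / (2 * eps)
      dpts <- xc %*% t(dR)
      J[, 3 + k] <- gx * dpts[, 1] + gy * dpts[, 2] + gz * dpts[, 3]
    }
    g <- crossprod(J, resid)
    H <- crossprod(J)
    improved <- FALSE
    for (try in 1:12) {
      Hd <- H + lambda * diag(diag(H) + 1e-12)
      delta <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      p_new <- p - as.numeric(delta)
      new <- cost_of(p_new)
      if (is.finite(new$cost) && new$cost < cost) {
        step_size <- max(abs(delta[1:3]), abs(delta[4:6]) * deg_scale)
        rel_dec <- (cost - new$cost) / max(cost, 1e-300)
        p <- p_new
        cost <- new$cost
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (step_size < step_tol || rel_dec < cost_tol) converged <- TRUE
        break
      } else {
        lambda <- lambda * 10
      }
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  registration_result(rigid_transform(p[1:3], p[4:6], ctr), cost, it,
                      converged = converged && is.finite(cost))
}

#' Resample a moving volume into the reference grid
#'
#' Trilinearly samples `volume` at the transformed positions of the
#' reference grid, i.e. undoes the object motion described by `transform`.
#' Out-of-support voxels take `fill` and are flagged in the validity mask
#' attached as attribute `"valid"`.
#'
#' @param volume Moving [ulm_volume()].
#' @param transform A [rigid_transform()] (object motion reference ->
#'   moving).
#' @param grid Optional [volume_grid()] / `ulm_volume` defining the output
#'   geometry; defaults to `volume`'s own grid.
#' @param fill Fill value outside the support. Default 0.
#' @return An [ulm_volume()] with attribute `valid` (logical array).
#' @export
resample_volume <- function(volume, transform, grid = NULL, fill = 0) {
  ref <- if (is.null(grid)) volume else grid
  shape <- if (inherits(ref, "ulm_volume")) dim(ref$data) else ref$shape
  origin <- ref$origin; pitch <- ref$pitch
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(shape[i]) - 1) * pitch[i])
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  s <- cpp_trilinear(as.numeric(volume$data), dim(volume$data),
                     mm_to_voxel(volume, transform_points(transform, pts)),
                     fill)
  out <- ulm_volume(array(s$values, shape), origin, pitch, volume$frame_time)
  attr(out, "valid") <- array(s$valid, shape)
  out
}

#' Motion-corrected (Lagrangian) accumulation of a frame sequence
#'
#' Each frame's voxel values are scattered, with trilinear weights, to the
#' reference-frame voxels at their motion-corrected physical positions (the
#' inverse of each frame's object motion), then reduced across frames.
#'
#' @param frames List of [ulm_volume()]s.
#' @param transforms List of per-frame [rigid_transform()]s (object motion
#'   reference -> frame), one per frame.
#' @param reducer `"sum"`, `"mean"` or `"max"`.
#' @param grid Optional output geometry (defaults to the first frame's).
#' @return An [ulm_volume()]; attribute `"counts"` holds the per-voxel
#'   accumulated weights used for normalisation.
#' @export
lagrangian_accumulate <- function(frames, transforms,
                                  reducer = c("sum", "mean", "max"),
                                  grid = NULL) {
  reducer <- match.arg(reducer)
  if (length(frames) != length(transforms))
    stop("one transform per frame is required")
  ref <- if (is.null(grid)) frames[[1]] else grid
  shape <- if (inherits(ref, "ulm_volume")) dim(ref$data) else ref$shape
  origin <- ref$origin; pitch <- ref$pitch
  acc <- array(0, shape); wts <- array(0, shape)
  mx <- array(-Inf, shape)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    inv <- invert_transform(transforms[[k]])
    # frame voxel at position x corresponds to reference position inv(x)
    pts_ref <- transform_points(inv, grid_points(f))
    vox <- sweep(sweep(pts_ref, 2, origin, "-"), 2, pitch, "/")
    if (reducer == "max") {
      idx <- round(vox)
      keep <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
        idx[, 1] < shape[1] & idx[, 2] < shape[2] & idx[, 3] < shape[3]
      lin <- 1 + idx[keep, 1] + shape[1] * (idx[keep, 2] + shape[2] * idx[keep, 3])
      vals <- as.numeric(f$data)[keep]
      o <- order(vals)
      mx[lin[o]] <- pmax(mx[lin[o]], vals[o])
      wts[lin] <- wts[lin] + 1
    } else {
      sp <- cpp_splat(shape, vox, as.numeric(f$data))
      acc <- acc + array(sp$acc, shape)
      wts <- wts + array(sp$wts, shape)
    }
  }
  out <- switch(reducer,
                sum = acc,
                mean = ifelse(wts > 0, acc / wts, 0),
                max = ifelse(is.finite(mx), mx, 0))
  res <- ulm_volume(out, origin, pitch, frames[[1]]$frame_time)
  attr(res, "counts") <- wts
  res
}

#' Serialise per-frame transforms as CSV
#' @param transforms List of [rigid_transform()]s.
#' @param converged Optional logical vector.
#' @param path Output CSV path.
#' @return The data frame, invisibly.
#' @export
write_transforms_csv <- function(transforms, path, converged = NULL) {
  df <- data.frame(
    frame_index = seq_along(transforms),
    tx_mm = vapply(transforms, function(t) t$translation[1], 0),
    ty_mm = vapply(transforms, function(t) t$translation[2], 0),
    tz_mm = vapply(transforms, function(t) t$translation[3], 0),
    rx_deg = vapply(transforms, function(t) t$rotation[1], 0),
    ry_deg = vapply(transforms, function(t) t$rotation[2], 0),
    rz_deg = vapply(transforms, function(t) t$rotation[3], 0),
    converged = if (is.null(converged)) TRUE else converged)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
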