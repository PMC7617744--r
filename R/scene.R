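#' Crossed-channel flow phantom scene
#'
#' Builds the world-frame geometry of the wall-less crossed-microchannel
#' phantom: two straight cylindrical channels crossing at a shallow angle, a
#' bright spherical landmark with two supporting lobes, diffuse tissue
#' speckle scatterers, and microbubble point scatterers seeded inside the
#' channels. The probe frame is right-handed with x = lateral,
#' y = elevational, z = depth (positive away from the probe); the phantom at
#' rest is expressed in the same frame.
#'
#' @param channel_radius Channel lumen radius (mm). Default 0.1 (200 um
#'   diameter: a 180 um template wire plus two 10 um conformal coatings).
#' @param crossing_angle_deg Angle between the two channel axes (deg).
#'   Default 30.
#' @param channel_depth Depth of the crossing point (mm). Default 20.
#' @param channel_half_length Half-length of each channel segment (mm).
#'   Default 8.
#' @param landmark_center Centre of the 1 mm landmark ball (mm). Defaults to
#'   2.5 mm elevationally offset from the crossing, slightly shallower.
#' @param landmark_radius Landmark ball radius (mm). Default 0.5.
#' @param landmark_amp Total landmark amplitude (a.u.), spread over the
#'   scatterers that sample the ball. Default 60.
#' @param lobe_offset Lateral offset of the two supporting lobes from the
#'   ball centre (mm). Default 1.8.
#' @param lobe_amp Per-lobe total amplitude. Default 20.
#' @param n_speckle Number of diffuse tissue scatterers. Default 2000.
#' @param speckle_extent Half-widths (x, y) and depth range (z_min, z_max)
#'   of the speckle block, as `c(hx, hy, zmin, zmax)` in mm.
#' @param speckle_amp_scale Rayleigh scale of speckle amplitudes. Default 1.
#' @param n_bubbles Number of concurrent microbubbles. Default 20.
#' @param bubble_amp Mean bubble amplitude. Default 8.
#' @param mean_flow_speed Cross-section-averaged flow speed in each channel
#'   (mm/s). Default 1.
#' @param seed Integer seed controlling speckle placement and bubble
#'   seeding/recycling. Default 1.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(channel_radius = 0.1,
                          crossing_angle_deg = 30,
                          channel_depth = 20,
                          channel_half_length = 8,
                          landmark_center = c(0, -2.5, channel_depth - 1.5),
                          landmark_radius = 0.5,
                          landmark_amp = 60,
                          lobe_offset = 1.8,
                          lobe_amp = 20,
                          n_speckle = 2000,
                          speckle_extent = c(12, 12, 12, 28),
                          speckle_amp_scale = 1,
                          n_bubbles = 20,
                          bubble_amp = 8,
                          mean_flow_speed = 1,
                          seed = 1L) {
  stopifnot(channel_radius > 0, channel_half_length > 0, landmark_radius > 0)
  half_ang <- crossing_angle_deg / 2 * pi / 180
  # both channels lie in a plane tilted out of pure lateral so that they are
  # separated elevationally away from the crossing; crossing at the origin
  # of the lateral/elevational axes at `channel_depth`.
  d1 <- c(cos(half_ang), sin(half_ang), 0)
  d2 <- c(cos(half_ang), -sin(half_ang), 0)
  center <- c(0, 0, channel_depth)
  channels <- list(
    list(p0 = center - channel_half_length * d1, dir = d1,
         length = 2 * channel_half_length),
    list(p0 = center - channel_half_length * d2, dir = d2,
         length = 2 * channel_half_length))

  rng <- local_rng(seed)
  # speckle
  sp <- with_rng(rng, {
    n <- n_speckle
    data.frame(
      x = stats::runif(n, -speckle_extent[1], speckle_extent[1]),
      y = stats::runif(n, -speckle_extent[2], speckle_extent[2]),
      z = stats::runif(n, speckle_extent[3], speckle_extent[4]),
      amp = speckle_amp_scale * sqrt(-2 * log(stats::runif(n))),
      kind = rep("speckle", n), stringsAsFactors = FALSE)
  })
  # landmark ball sampled by scatterers on a Fibonacci-like shell + centre
  nl <- 32L
  gold <- pi * (3 - sqrt(5))
  k <- seq_len(nl) - 0.5
  zs <- 1 - 2 * k / nl
  rs <- sqrt(pmax(0, 1 - zs^2))
  ball <- data.frame(
    x = landmark_center[1] + 0.8 * landmark_radius * rs * cos(gold * k),
    y = landmark_center[2] + 0.8 * landmark_radius * rs * sin(gold * k),
    z = landmark_center[3] + 0.8 * landmark_radius * zs,
    amp = landmark_amp / (nl + 4), kind = "landmark", stringsAsFactors = FALSE)
  ball <- rbind(ball, data.frame(x = landmark_center[1], y = landmark_center[2],
                                 z = landmark_center[3], amp = 4 * landmark_amp / (nl + 4),
                                 kind = "landmark", stringsAsFactors = FALSE))
  # supporting lobes: two small bright ellipsoid clusters flanking the ball
  lobes <- do.call(rbind, lapply(c(-1, 1), function(s) {
    nn <- 12L
    th <- seq(0, 2 * pi, length.out = nn + 1L)[-1]
    data.frame(
      x = landmark_center[1] + s * lobe_offset + 0.6 * cos(th),
      y = landmark_center[2] + 0.25 * sin(th),
      z = landmark_center[3] + 0.4 * sin(2 * th),
      amp = lobe_amp / nn, kind = "lobe", stringsAsFactors = FALSE)
  }))
  scatterers <- rbind(sp, ball, lobes)

  # bubbles: uniform over channels, radial position area-uniform
  bubbles <- with_rng(rng, {
    ch <- sample(seq_along(channels), n_bubbles, replace = TRUE)
    data.frame(
      channel = ch,
      s = stats::runif(n_bubbles, 0, vapply(channels[ch], `[[`, 0, "length")),
      r = channel_radius * sqrt(stats::runif(n_bubbles)),
      phi = stats::runif(n_bubbles, 0, 2 * pi),
      amp = bubble_amp * (0.7 + 0.6 * stats::runif(n_bubbles)))
  })

  structure(list(channels = channels, channel_radius = channel_radius,
                 landmark_center = landmark_center,
                 landmark_radius = landmark_radius,
                 scatterers = scatterers, bubbles = bubbles,
                 mean_flow_speed = mean_flow_speed, seed = as.integer(seed),
                 time = 0, displacement = c(0, 0, 0)),
            class = "phantom_scene")
}

# isolated RNG stream helpers: scene construction and bubble recycling use
# their own stream so scene evaluation never disturbs the caller's RNG
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

poiseuille_speed <- function(mean_speed, r, radius) {
  2 * mean_speed * (1 - (r / radius)^2)
}

bubble_positions <- function(scene) {
  b <- scene$bubbles
  pos <- matrix(0, nrow(b), 3)
  for (ci in seq_along(scene$channels)) {
    idx <- which(b$channel == ci)
    if (!length(idx)) next
    ch <- scene$channels[[ci]]
    n1 <- perp_basis(ch$dir)
    ax <- outer(b$s[idx], ch$dir) + matrix(ch$p0, length(idx), 3, byrow = TRUE)
    rad <- b$r[idx] * (cos(b$phi[idx]) %o% n1$u + sin(b$phi[idx]) %o% n1$v)
    pos[idx, ] <- ax + rad
  }
  pos
}

perp_basis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3], d[1] * a[2] - d[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3], d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Scene state at a given time
#'
#' Rigidly displaces the phantom by the stage profile displacement at `t`
#' along the profile axis, and advects the microbubbles along their channels
#' with a parabolic (Poiseuille) velocity profile: the axial speed at radial
#' offset r is `2 * mean_flow_speed * (1 - (r/R)^2)`. Bubbles that exit a
#' channel are recycled at its inlet with a freshly drawn radial offset; the
#' recycling draw depends only on the bubble identity and its lap count, so
#' `scene_at_time` is deterministic in `t`.
#'
#' @param scene A [phantom_scene()].
#' @param profile A [motion_profile()] for the stage, or `NULL` for a static
#'   phantom.
#' @param t Time (s), scalar, `t >= 0`.
#' @param flow_speed Optional override of the scene's mean flow speed (mm/s).
#' @return A `phantom_scene` whose geometry is expressed at time `t`, with
#'   fields `time` and `displacement` recording the rigid stage offset.
#' @export
scene_at_time <- function(scene, profile, t, flow_speed = NULL) {
  stopifnot(inherits(scene, "phantom_scene"), length(t) == 1L, t >= 0)
  vbar <- if (is.null(flow_speed)) scene$mean_flow_speed else flow_speed
  out <- scene
  # advect bubbles (in channel/world coordinates, before rigid displacement)
  b <- scene$bubbles
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      ci <- b$channel[i]
      len <- scene$channels[[ci]]$length
      r <- b$r[i]
      v <- poiseuille_speed(vbar, r, scene$channel_radius)
      s_new <- b$s[i] + v * t
      lap <- 0L
      # recycle: each lap re-draws the radial offset, which changes the speed
      while (s_new > len) {
        lap <- lap + 1L
        s_new <- s_new - len
        draw <- recycle_draw(scene$seed, i, lap)
        frac_left <- s_new / len   # fraction of residual distance, carried over
        r <- scene$channel_radius * sqrt(draw[1])
        v_new <- poiseuille_speed(vbar, r, scene$channel_radius)
        s_new <- frac_left * len * (v_new / max(v, 1e-9))
        s_new <- s_new %% len
        b$phi[i] <- 2 * pi * draw[2]
        v <- v_new
      }
      b$s[i] <- s_new
      b$r[i] <- r
    }
    out$bubbles <- b
  }
  # rigid stage displacement
  disp <- if (is.null(profile)) c(0, 0, 0) else
    profile_displacement(profile, t) * profile$axis_direction
  out$time <- t
  out$displacement <- disp
  out
}

# deterministic per-bubble, per-lap uniform draws (two in [0,1))
recycle_draw <- function(seed, bubble, lap) {
  h <- (as.double(seed) * 2654435761 + bubble * 40503 + lap * 69621) %% 2147483647
  u1 <- ((h * 16807) %% 2147483647)
  u2 <- ((u1 * 16807) %% 2147483647)
  c(u1, u2) / 2147483647
}

#' Scatterer table of a scene
#'
#' All point scatterers (speckle, landmark, lobes, bubbles) in world
#' coordinates at the scene's current time, including the rigid stage
#' displacement.
#'
#' @param scene A [phantom_scene()], typically from [scene_at_time()].
#' @return `data.frame` with columns `x_mm`, `y_mm`, `z_mm`, `amplitude`,
#'   `kind`.
#' @export
scene_scatterers <- function(scene) {
  s <- scene$scatterers
  out <- data.frame(x_mm = s$x, y_mm = s$y, z_mm = s$z,
                    amplitude = s$amp, kind = s$kind,
                    stringsAsFactors = FALSE)
  if (nrow(scene$bubbles)) {
    bp <- bubble_positions(scene)
    out <- rbind(out, data.frame(x_mm = bp[, 1], y_mm = bp[, 2], z_mm = bp[, 3],
                                 amplitude = scene$bubbles$amp, kind = "bubble",
                                 stringsAsFactors = FALSE))
  }
  d <- scene$displacement
  out$x_mm <- out$x_mm + d[1]
  out$y_mm <- out$y_mm + d[2]
  out$z_mm <- out$z_mm + d[3]
  out
}

#' Landmark centre at the scene's current time
#' @param scene A [phantom_scene()].
#' @return World-frame landmark centre (mm 3-vector).
#' @export
scene_landmark <- function(scene) {
  scene$landmark_center + scene$displacement
}
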