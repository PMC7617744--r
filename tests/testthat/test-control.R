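test_that("robot moves follow trapezoids: peak speed, durations, triangular regime", {
  st <- robot_state()
  st <- robot_move(st, c(10, 0, 0), t_start = 0)
  seg <- st$moves[[1]]$seg
  expect_equal(segment_peak_speed(seg), 50)     # 10 mm just reaches vmax
  expect_equal(st$busy_until, segment_duration(seg))
  # 2 mm triangular move: duration 2 sqrt(2 / 250)
  st2 <- robot_move(robot_state(), c(0, 2, 0), t_start = 1)
  expect_equal(st2$busy_until - 1, 2 * sqrt(2 / 250), tolerance = 1e-12)
  expect_lt(segment_peak_speed(st2$moves[[1]]$seg), 50)
  # zero-length move completes instantly
  st3 <- robot_move(robot_state(), c(0, 0, 0), t_start = 2)
  expect_equal(st3$busy_until, 2)
  expect_equal(robot_pose_at(st3, 5)[1, ], c(0, 0, 0))
  # commanding a busy robot is an error (dropped upstream)
  expect_error(robot_move(st, c(0, 0, 0), t_start = 0.1), "busy")
})

test_that("safety workspace admits inside and boundary poses, withholds outside", {
  ws <- safety_workspace()
  expect_false(clamp_command(ws, c(0, 0, 0))$withheld)
  expect_true(clamp_command(ws, c(60, 0, 0))$withheld)
  expect_false(clamp_command(ws, c(50, 0, 0))$withheld)   # closed interval
  expect_true(clamp_command(ws, c(0, 0, 5.01))$withheld)
  ws2 <- safety_workspace(center = c(10, 0, 0))
  expect_false(clamp_command(ws2, c(60, 0, 0))$withheld)
})

test_that("crop arithmetic matches the online processing volume", {
  big <- ulm_volume(array(stats::rnorm(50^3), c(50, 50, 50)),
                    origin = c(-10, -10, 10), pitch = 0.4)
  cr <- crop_volume(big, c(0, 0, 20), 12.5)
  expect_equal(dim(cr$data), c(31, 31, 31))
  expect_equal(prod(dim(cr$data)), 29791)     # about 3e4 voxels
  expect_lt(abs(prod(dim(cr$data)) - 3e4), 0.01 * 3e4)
  # cropped voxels match the parent volume
  ctr <- big$origin + (dim(big$data) - 1) / 2 * big$pitch
  full <- crop_volume(big, ctr, 50 * 0.4)
  expect_equal(full$data, big$data)
  i0 <- round((cr$origin - big$origin) / big$pitch)
  expect_equal(cr$data[1, 1, 1], big$data[i0[1] + 1, i0[2] + 1, i0[3] + 1])
  expect_equal(cr$data[5, 7, 2],
               big$data[i0[1] + 5, i0[2] + 7, i0[3] + 2])
  expect_error(crop_volume(big, c(0, 0, 10.2), 12.5), "exceeds")
})

test_that("acquisition timestamps stay uniform whatever the latencies do", {
  sc <- tiny_scene(seed = 6)
  p <- build_protocol("single_speed", 3, n_round_trips = 1)
  log <- run_async_loop(sc, p, detection = "ideal", duration = 4, seed = 3)
  dt <- diff(log$frames$t_s)
  expect_equal(dt, rep(1 / 85, length(dt)))
  # every issued command lies inside the safety workspace
  issued <- log$cycles[log$cycles$cmd_issued, ]
  expect_true(all(abs(issued$det_dx_mm +
                        log$frames$robot_x_mm[1]) <= 50 + 20))
  expect_true(all(!issued$withheld))
})

test_that("a static target draws essentially zero commands", {
  sc <- tiny_scene(seed = 8)
  p_static <- motion_profile(list(trap_segment(100, 1, 3, 1)))  # moves after end
  log <- run_async_loop(sc, p_static, detection = "ideal",
                        detection_noise_sd = 0.01, duration = 3, seed = 5)
  det <- sqrt(log$cycles$det_dx_mm^2 + log$cycles$det_dy_mm^2)
  expect_lt(max(det), 0.05)
  # the probe only jitters by the detection noise it chases
  expect_lt(max(log$frames$residual_mm), 0.06)
})

test_that("with zero latency and an instantaneous robot the residual is one frame of motion", {
  sc <- tiny_scene(seed = 9)
  p <- build_protocol("single_speed", 5, n_round_trips = 1)
  tm <- loop_timings(beamform_latency = 0, registration_latency = c(0, 0),
                     command_latency = 0)
  log <- run_async_loop(sc, p, timings = tm, detection = "ideal",
                        detection_noise_sd = 0, duration = 6,
                        robot_accel = 1e7, robot_vmax = 1e5, seed = 2)
  expect_lte(max(log$frames$residual_mm), 5 * (2 / 85) + 1e-6)
})

test_that("doubling all latencies never reduces the mean residual", {
  sc <- tiny_scene(seed = 10)
  p <- build_protocol("single_speed", 4, n_round_trips = 1)
  mean_res <- function(scale, seed) {
    tm <- loop_timings(beamform_latency = 0.04 * scale,
                       registration_latency = c(0.04, 0.3) * scale,
                       command_latency = 0.03 * scale)
    log <- run_async_loop(sc, p, timings = tm, detection = "ideal",
                          duration = profile_duration(p) + 1, seed = seed)
    residual_stats(detect_onset(series_from_log(log)))$mean_mm
  }
  base <- vapply(1:4, function(s) mean_res(1, s), 0)
  slow <- vapply(1:4, function(s) mean_res(2, s), 0)
  expect_gte(mean(slow), mean(base))
})

test_that("image-based detection in the loop agrees with ideal geometric detection", {
  sc <- phantom_scene(n_speckle = 600, n_bubbles = 8, seed = 3)
  p <- build_protocol("single_speed", 3, n_round_trips = 1)
  li <- run_async_loop(sc, p, detection = "image", seed = 4,
                       duration = profile_duration(p) + 1)
  lg <- run_async_loop(sc, p, detection = "ideal", seed = 4,
                       duration = profile_duration(p) + 1)
  mi <- residual_stats(detect_onset(series_from_log(li)))$mean_mm
  mg <- residual_stats(detect_onset(series_from_log(lg)))$mean_mm
  expect_lt(abs(mi - mg) / mg, 0.35)
})

test_that("tracking keeps the landmark in view where a fixed probe loses it", {
  sc <- tiny_scene(seed = 11)
  p <- build_protocol("mixed", n_round_trips = 1)
  fixed <- run_async_loop(sc, p, tracking = FALSE, seed = 1)
  tracked <- run_async_loop(sc, p, detection = "ideal", seed = 1)
  expect_lt(mean(fixed$frames$landmark_in_fov), 0.8)
  expect_gte(mean(tracked$frames$landmark_in_fov), 0.95)
})
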