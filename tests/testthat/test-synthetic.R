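# The ground-truthed scene generator.

test_that("noiseless walker has exact stance intervals and hip displacement", {
  p <- walker_params(mode = "overground", speed_ms = 1, stride_hz = 1,
                     duty_factor = 0.6, duration_s = 5, rate = frame_rate(50),
                     noise_sd_m = 0, dropout = 0, seed = 1,
                     points_per_segment = 20L, background_points = 50L)
  g <- generate_walker(p)
  expect_length(g$sequence, 250L)
  st <- g$truth$stance$left
  expect_identical(st$start, seq(1L, by = 50L, length.out = 5L))
  expect_true(all(st$end - st$start == 30L))
  hip_x <- g$truth$markers$hip[, 1L]
  expect_equal(hip_x[250L] - hip_x[1L], 1 * (249 / 50), tolerance = 1e-12)
  # right foot is phase-shifted by half a stride
  str <- g$truth$stance$right
  expect_true(all((str$start[-1L] - st$start[1L]) %% 50L == 25L))
})

test_that("treadmill walker stance velocity is the belt speed, +X", {
  p <- walker_params(mode = "treadmill", speed_ms = 0.7, stride_hz = 1,
                     duration_s = 4, rate = frame_rate(50), noise_sd_m = 0,
                     seed = 2, points_per_segment = 20L, background_points = 50L)
  g <- generate_walker(p)
  mt5 <- g$truth$markers$mt5_l
  v <- diff(mt5[, 1L]) * 50
  st <- g$truth$stance$left
  in_stance <- unlist(lapply(seq_len(nrow(st)), function(i)
    st$start[i]:(st$end[i] - 2L)))   # interior stance differences
  expect_equal(v[in_stance], rep(0.7, length(in_stance)), tolerance = 1e-9)
  # hip stays near its station
  expect_lt(diff(range(g$truth$markers$hip[, 1L])), 0.01)
})

test_that("an applied similarity transform scales all pairwise distances", {
  base <- walker_params(duration_s = 1, rate = frame_rate(20), noise_sd_m = 0,
                        seed = 3, points_per_segment = 15L,
                        background_points = 40L)
  scaled <- base
  scaled$transform <- similarity_transform(s = 2.5)
  g0 <- generate_walker(base)
  g1 <- generate_walker(scaled)
  p0 <- g0$sequence$frames[[5L]]$points[1:40, ]
  p1 <- g1$sequence$frames[[5L]]$points[1:40, ]
  expect_equal(as.numeric(stats::dist(p1)), 2.5 * as.numeric(stats::dist(p0)),
               tolerance = 1e-9)
})

test_that("generation is deterministic in the seed", {
  p <- walker_params(duration_s = 1, rate = frame_rate(20), seed = 5,
                     noise_sd_m = 0.005, dropout = 0.2, transform = "random",
                     points_per_segment = 15L, background_points = 40L)
  g1 <- generate_walker(p)
  g2 <- generate_walker(p)
  expect_identical(g1$sequence$frames[[10L]]$points,
                   g2$sequence$frames[[10L]]$points)
  expect_identical(g1$truth$transform, g2$truth$transform)
  p2 <- p; p2$seed <- 6L
  g3 <- generate_walker(p2)
  expect_false(identical(g1$sequence$frames[[10L]]$points,
                         g3$sequence$frames[[10L]]$points))
})

test_that("same seed writes byte-identical PLY files and ground truth", {
  p <- walker_params(duration_s = 0.5, rate = frame_rate(20), seed = 9,
                     noise_sd_m = 0.005, transform = "random",
                     points_per_segment = 15L, background_points = 40L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(generate_walker(p), d1)
  write_scenario(generate_walker(p), d2)
  for (f in list.files(d1)) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
})

test_that("dropout removes a contiguous sector, not the whole cluster", {
  p0 <- walker_params(duration_s = 0.25, rate = frame_rate(20), seed = 4,
                      noise_sd_m = 0, dropout = 0,
                      points_per_segment = 200L, background_points = 40L)
  p3 <- p0; p3$dropout <- 0.3
  n0 <- nrow(generate_walker(p0)$sequence$frames[[1L]]$points)
  n3 <- nrow(generate_walker(p3)$sequence$frames[[1L]]$points)
  removed <- (n0 - n3) / (8L * 200L)   # fraction of body points removed
  expect_gt(removed, 0.2)
  expect_lt(removed, 0.4)
})

test_that("walker rejects geometrically impossible strides", {
  expect_error(
    generate_walker(walker_params(speed_ms = 3, stride_hz = 1,
                                  duration_s = 1, rate = frame_rate(20),
                                  points_per_segment = 10L,
                                  background_points = 20L)),
    class = "parameter_error")
})

test_that("flyer head displacement matches speed, climb and heading", {
  p <- flyer_params(ground_speed_ms = 2, climb_rate_ms = 0.5, heading_deg = 0,
                    duration_s = 2, rate = frame_rate("30p"), noise_sd_m = 0,
                    seed = 1, points_per_segment = 20L, background_points = 40L)
  g <- generate_flyer(p)
  h <- g$truth$markers$head
  dt <- g$truth$times[length(g$truth$times)] - g$truth$times[1L]
  expect_equal(h[nrow(h), 1L] - h[1L, 1L], 2 * dt, tolerance = 1e-9)
  expect_equal(h[nrow(h), 3L] - h[1L, 3L], 0.5 * dt, tolerance = 1e-9)

  # wingtip height relative to the body is the configured flap amplitude
  rel_z <- g$truth$markers$wingtip_l[, 3L] - g$truth$markers$body[, 3L]
  tt <- g$truth$times
  amp <- sqrt(sum(stats::lm.fit(cbind(sin(2 * pi * p$flap_hz * tt),
                                      cos(2 * pi * p$flap_hz * tt)),
                                rel_z)$coefficients^2))
  expect_equal(amp, p$wingtip_amplitude_m, tolerance = 1e-9)

  p37 <- flyer_params(heading_deg = 37, duration_s = 2, noise_sd_m = 0,
                      seed = 2, points_per_segment = 20L,
                      background_points = 40L)
  g37 <- generate_flyer(p37)
  xy <- g37$truth$markers$head[, 1:2]
  d <- xy[nrow(xy), ] - xy[1L, ]
  expect_equal(atan2(d[2L], d[1L]) * 180 / pi, 37, tolerance = 1e-6)
})

test_that("synthetic rigs invert through the calibration pathway", {
  f <- withr::local_tempfile()
  rig <- generate_bundler_file(2, spacing_m = 2, scale_s = 4, seed = 1, path = f)
  cams <- read_bundler(f)
  expect_equal(camera_separations(cams), 0.5, tolerance = 1e-9)
  expect_equal(scale_from_camera_separation(cams, rig$physical_separations), 4,
               tolerance = 1e-9)

  g <- withr::local_tempfile()
  generate_bundler_file(5, spacing_m = 1.3, scale_s = 0.7, seed = 8, path = g)
  for (cam in read_bundler(g)$cameras)
    expect_lt(sqrt(sum((cam$R %*% cam$centre + cam$t)^2)), 1e-10)
})

test_that("ground truth serialises and restores losslessly", {
  p <- walker_params(duration_s = 0.5, rate = frame_rate(20), seed = 7,
                     transform = "random", points_per_segment = 10L,
                     background_points = 20L)
  g <- generate_walker(p)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(g$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back$transform$R, g$truth$transform$R)
  expect_equal(back$transform$s, g$truth$transform$s)
  expect_equal(back$markers$hip, unname(g$truth$markers$hip))
  expect_equal(back$stance$left, g$truth$stance$left)
  expect_equal(back$scene$pole_indices, g$truth$scene$pole_indices)
  expect_equal(back$frame_rate$num, g$truth$frame_rate$num)
})

test_that("full noiseless pipeline closure: generate, orient, calibrate, digitise, analyse", {
  p <- walker_params(mode = "overground", speed_ms = 0.85, duration_s = 4,
                     rate = frame_rate(50), noise_sd_m = 0, dropout = 0,
                     seed = 10, transform = "random",
                     points_per_segment = 30L, background_points = 80L)
  g <- generate_walker(p)
  tr <- g$truth
  f1 <- g$sequence$frames[[1L]]
  R <- orient_cloud(f1, selection(indices = tr$scene$pole_indices),
                    selection(indices = tr$scene$rail_indices),
                    up_hint = as.numeric(tr$transform$R %*% c(0, 0, 1)),
                    forward_hint = as.numeric(tr$transform$R %*% c(1, 0, 0)))
  expect_lt(rot_angle(R$R %*% tr$transform$R), 1e-6)

  fb <- withr::local_tempfile()
  rig <- generate_bundler_file(4, 2, scale_s = tr$scale_m_per_unit,
                               seed = p$seed, path = fb)
  s <- scale_from_camera_separation(read_bundler(fb), rig$physical_separations)
  expect_lt(abs(s / tr$scale_m_per_unit - 1), 1e-9)

  # true marker track recovers the mean velocity to machine precision
  truth_ts <- time_series(tr$times, tr$markers$head[, 1L])
  expect_lt(abs(mean_velocity_regression(truth_ts)$slope / 0.85 - 1), 1e-9)

  dig <- digitise_truth_markers(g, "head")
  ts <- marker_time_series(dig$series$head, p$rate, "x")
  slope <- mean_velocity_regression(ts)$slope
  expect_lt(abs(slope / 0.85 - 1), 1e-3)
})
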