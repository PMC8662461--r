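test_that("range resolution follows c/(2B)", {
  expect_equal(signif(range_resolution(3e9), 2), 0.05)
  expect_equal(range_resolution(800e6), 0.18737, tolerance = 1e-4)
  expect_equal(range_resolution(c(1e9, 2e9)), 299792458 / (2 * c(1e9, 2e9)))
  b <- 10^seq(8, 11, length.out = 20)
  expect_true(all(diff(range_resolution(b)) < 0))
  expect_error(range_resolution(0))
})

test_that("free-space gain follows 20 log10(f_high/f_low)", {
  expect_equal(free_space_gain(77e9, 24e9), 10.13, tolerance = 0.005)
  expect_equal(free_space_gain(5e9, 5e9), 0)
  expect_equal(free_space_gain(48e9, 24e9), 20 * log10(2), tolerance = 1e-12)
  expect_equal(free_space_gain(48e9, 24e9), 6.0206, tolerance = 1e-4)
  expect_error(free_space_gain(-1, 1))
})

test_that("frame_to_map recovers a noiseless target within one bin", {
  radar <- default_radar_quiet()
  pos <- c(-0.4, 2.7)
  m <- frame_to_map(synthesize_beat_signal(pos, clutter_scene(), radar,
                                           target_amplitude = 1))
  ij <- which(m$values == max(m$values), arr.ind = TRUE)
  r_true <- sqrt(sum(pos^2)); u_true <- pos[1] / r_true
  expect_lt(abs(m$range_m[ij[1]] - r_true), radar$range_bin_m)
  expect_lt(abs(m$u[ij[2]] - u_true), radar$u_bin)
  expect_error(frame_to_map(unclass(matrix(0i, 4, 4)), radar), "channels")
})

test_that("two well-separated targets give two local maxima at their cells", {
  radar <- default_radar_quiet()
  scene <- clutter_scene(range = 2, azimuth_deg = -20, amplitude = 1)
  m <- frame_to_map(synthesize_beat_signal(c(0.8, 5), scene, radar,
                                           target_amplitude = 1))
  # brute-force peak search: strictly greater than the 8 neighbours
  v <- m$values
  peaks <- which(
    v > rbind(-Inf, v[-nrow(v), ]) & v > rbind(v[-1, ], -Inf) &
    v > cbind(-Inf, v[, -ncol(v)]) & v > cbind(v[, -1], -Inf) &
    v > 0.25 * max(v), arr.ind = TRUE)
  expect_gte(nrow(peaks), 2)
  r1 <- 2; u1 <- sin(-20 * pi / 180)
  r2 <- sqrt(0.8^2 + 25); u2 <- 0.8 / r2
  hit <- function(r, u) any(abs(m$range_m[peaks[, 1]] - r) < radar$range_bin_m &
                            abs(m$u[peaks[, 2]] - u) < radar$u_bin)
  expect_true(hit(r1, u1))
  expect_true(hit(r2, u2))
})

test_that("clutter statistics are per-cell sample moments", {
  radar <- radar_config(n_tx = 1L, n_rx = 4L, n_range_bins = 8, n_angle_bins = 8)
  f <- matrix(runif(64), 8, 8)
  frames <- lapply(1:5, function(i) range_azimuth_frame(f, radar))
  cs <- estimate_clutter(frames)
  expect_equal(cs$mean, f)
  expect_true(all(cs$std == 0))
  expect_equal(cs$n_frames, 5)
  expect_error(estimate_clutter(frames[1]), "at least 2")

  # i.i.d. noise frames: per-cell mean within 4 sd/sqrt(n) of the truth
  set.seed(21)
  n <- 1000; mu <- 3; sigma <- 0.5
  arr <- array(rnorm(n * 16, mu, sigma), c(n, 4, 4))
  cs2 <- estimate_clutter(arr)
  expect_true(all(abs(cs2$mean - mu) < 4 * sigma / sqrt(n)))
  expect_true(all(abs(cs2$std - sigma) < 4 * sigma / sqrt(n)))
})

test_that("clutter normalization standardizes cell-wise", {
  radar <- radar_config(n_tx = 1L, n_rx = 2L, n_range_bins = 4, n_angle_bins = 4)
  mu <- matrix(2, 4, 4)
  cs <- structure(list(mean = mu, std = matrix(0.5, 4, 4), n_frames = 10),
                  class = "clutter_stats")
  f <- range_azimuth_frame(mu, radar)
  expect_true(all(normalize_frame(f, cs)$values == 0))

  v <- mu; v[2, 3] <- 2 + 10 * 0.5
  d <- normalize_frame(range_azimuth_frame(v, radar), cs)
  expect_equal(d$values[2, 3], 10)

  # zero-variance cells are guarded by eps, not Inf
  cs0 <- structure(list(mean = mu, std = matrix(0, 4, 4), n_frames = 10),
                   class = "clutter_stats")
  d0 <- normalize_frame(range_azimuth_frame(mu + 1, radar), cs0, eps = 1e-12)
  expect_true(all(is.finite(d0$values)))

  cs_bad <- structure(list(mean = matrix(0, 3, 3), std = matrix(1, 3, 3)),
                      class = "clutter_stats")
  expect_error(normalize_frame(f, cs_bad), "shape")
})

test_that("standardized background ensemble has mean 0 and sd 1", {
  radar <- radar_config(noise_sigma = 0.1, n_tx = 2L, n_rx = 8L,
                        n_range_bins = 32, n_angle_bins = 16)
  scene <- arena_clutter_scene()
  set.seed(31)
  bg <- lapply(1:500, function(i) synthesize_map(NULL, scene, radar))
  cl <- estimate_clutter(bg[1:250])
  d <- vapply(bg[251:500], function(f) {
    v <- normalize_frame(f, cl)$values
    c(mean(v), stats::sd(v))
  }, numeric(2))
  expect_lt(abs(mean(d[1, ])), 0.05)
  expect_true(mean(d[2, ]) > 0.9 && mean(d[2, ]) < 1.1)
})

test_that("detection applies threshold, tie rule and refinement", {
  radar <- radar_config(n_tx = 1L, n_rx = 8L, n_range_bins = 16, n_angle_bins = 8)
  z <- matrix(0, 16, 8)
  f <- range_azimuth_frame(z, radar)
  f$values <- z
  expect_false(detect_target(f, 5)$valid)

  v <- z; v[7, 4] <- 10
  f$values <- v
  d <- detect_target(f, 5)
  expect_true(d$valid)
  expect_equal(d$range, radar$range_bin_m * 6)
  expect_equal(d$score, 10)

  # two equal maxima: smaller range, then smaller angle index wins
  v2 <- z; v2[5, 6] <- 8; v2[9, 2] <- 8
  f$values <- v2
  expect_equal(detect_target(f, 5)$range, radar$range_bin_m * 4)
  v3 <- z; v3[5, 6] <- 8; v3[5, 2] <- 8
  f$values <- v3
  d3 <- detect_target(f, 5)
  expect_equal(d3$u, angle_bins(radar)$u[2])
})

test_that("detection probability is non-decreasing in target amplitude", {
  radar <- radar_config(noise_sigma = 0.3, n_tx = 2L, n_rx = 8L,
                        n_range_bins = 96, n_angle_bins = 16)
  scene <- arena_clutter_scene()
  set.seed(41)
  cl <- estimate_clutter(lapply(1:100, function(i)
    synthesize_map(NULL, scene, radar)))
  pd <- vapply(c(0, 1, 2, 4), function(a) {
    mean(vapply(1:200, function(i) {
      f <- synthesize_map(c(0.3, 3.1), scene, radar, target_amplitude = a)
      detect_target(normalize_frame(f, cl), 5)$valid
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(pd) >= -0.03))  # binomial slack at 200 frames per rung
  expect_gt(pd[4], pd[1])
  expect_equal(pd[4], 1)
})

test_that("track assembly converts, gap-fills and clamps", {
  arena <- arena_config()
  det <- data.frame(time = c(0, 1, 2), range = c(1, 1.5, 2),
                    azimuth_deg = 0, valid = TRUE)
  tr <- assemble_track(det, rate = 1, arena)
  expect_equal(tr$y, c(1, 1.5, 2))
  expect_equal(tr$x, c(0, 0, 0))

  # one missing frame between (0,1) and (0,2): midpoint fill
  det2 <- data.frame(time = 0:2, range = c(1, NA, 2), azimuth_deg = 0,
                     valid = c(TRUE, FALSE, TRUE))
  tr2 <- assemble_track(det2, rate = 1, arena)
  expect_equal(tr2$y[2], 1.5)
  expect_false(tr2$valid[2])

  # leading/trailing gaps hold the nearest valid fix
  det3 <- data.frame(time = 0:3, range = c(NA, 2, NA, NA), azimuth_deg = 0,
                     valid = c(FALSE, TRUE, FALSE, FALSE))
  tr3 <- assemble_track(det3, rate = 1, arena)
  expect_equal(tr3$y, rep(2, 4))

  expect_error(assemble_track(
    data.frame(time = 0:1, range = NA, azimuth_deg = 0, valid = FALSE),
    rate = 1, arena), "no valid detections")

  # out-of-arena fixes are clamped and flagged
  det4 <- data.frame(time = 0, range = 8, azimuth_deg = 0, valid = TRUE)
  tr4 <- assemble_track(det4, rate = 1, arena)
  expect_equal(tr4$y, 7)
  expect_true(tr4$clamped)
})

test_that("20% dropped frames on a straight track refill within one bin", {
  arena <- arena_config()
  rate <- 50
  tms <- (0:199) / rate
  x <- rep(0.2, 200); y <- 1 + 0.5 * tms
  r <- sqrt(x^2 + y^2); th <- asin(x / r) * 180 / pi
  set.seed(9)
  drop <- sample(200, 40)
  det <- data.frame(time = tms, range = r, azimuth_deg = th, valid = TRUE)
  det$valid[drop] <- FALSE
  det$range[drop] <- NA
  tr <- assemble_track(det, rate, arena)
  rmse <- sqrt(mean((tr$x - x)^2 + (tr$y - y)^2))
  expect_lt(rmse, radar_config()$range_bin_m)
})

test_that("end-to-end noiseless recovery is within half a bin (20 positions)", {
  radar <- default_radar_quiet()
  set.seed(5)
  pos <- cbind(runif(20, -0.9, 0.9), runif(20, 0.8, 6.8))
  for (i in seq_len(20)) {
    m <- frame_to_map(synthesize_beat_signal(pos[i, ], clutter_scene(), radar,
                                             target_amplitude = 1))
    d <- detect_target(m, threshold = 0.1)
    r_true <- sqrt(sum(pos[i, ]^2)); u_true <- pos[i, 1] / r_true
    expect_true(d$valid)
    expect_lt(abs(d$range - r_true), radar$range_bin_m / 2)
    expect_lt(abs(d$u - u_true), radar$u_bin / 2)
  }
})

test_that("full session tracking recovers the ground truth trajectory", {
  arena <- arena_config(phase_durations = c(2, 4, 4))
  radar <- radar_config(noise_sigma = 0.05, n_range_bins = 160,
                        n_angle_bins = 32, frame_rate = 10)
  s <- generate_session(arena, radar, sheep_movement_model(),
                        covariate_spec(), seed = 3, frames = "map",
                        n_background = 100)
  expect_equal(length(s$frames), 10 * 10)
  tr <- track_session(s, threshold = 5)
  gt <- s$ground_truth
  err <- sqrt((tr$x - gt$x)^2 + (tr$y - gt$y)^2)
  expect_lt(stats::median(err), 2 * radar$range_bin_m)
  expect_gt(mean(tr$valid), 0.9)
})
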