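test_that("window segmentation follows the 1-s / half-window rule", {
  tr <- straight_trajectory(duration = 60 - 1 / 50)   # exactly 60 s of samples
  w <- segment_windows(tr)
  expect_length(w, 60)
  expect_true(all(vapply(w, nrow, 1L) == 50))

  tr2 <- straight_trajectory(duration = 60.4 - 1 / 50) # trailing 0.4 s dropped
  expect_length(segment_windows(tr2), 60)

  tr3 <- straight_trajectory(duration = 60.6 - 1 / 50) # trailing 0.6 s kept
  expect_length(segment_windows(tr3), 61)

  expect_error(segment_windows(straight_trajectory(duration = 0.3)),
               "shorter than one window")

  # windows never span a phase boundary
  a <- arena_config(phase_durations = c(2, 3, 3))
  tms <- seq(0, 8 - 1 / 50, by = 1 / 50)
  trp <- trajectory(tms, rep(0, length(tms)), rep(1, length(tms)),
                    phase = assign_phases(tms, a), rate = 50)
  wp <- segment_windows(trp)
  expect_true(all(vapply(wp, function(x) length(unique(x$phase)), 1L) == 1))
})

test_that("window features match hand-computed values", {
  # straight path at 0.5 m/s for 1 s
  tr <- straight_trajectory(speed = 0.5, duration = 1 - 1 / 50)
  f <- window_features(tr)
  expect_equal(f$mean_speed, 0.5, tolerance = 1e-9)
  expect_equal(f$sinuosity, 1)
  expect_equal(f$lateral_speed, 0)
  expect_equal(f$longitudinal_speed, 0.5, tolerance = 1e-9)

  # L-shaped path: (0,0) -> (1,0) -> (1,1): path 2, net sqrt(2)
  w <- trajectory(c(0, 1, 2), c(0, 1, 1), c(0, 0, 1), rate = 1)
  f2 <- window_features(w)
  expect_equal(f2$path_length, 2)
  expect_equal(f2$sinuosity, sqrt(2), tolerance = 0.01)

  # stationary window: degenerate ratio guarded to 1
  w0 <- trajectory(c(0, 0.5, 1), rep(0.2, 3), rep(3, 3), rate = 2)
  f0 <- window_features(w0)
  expect_equal(f0$mean_speed, 0)
  expect_equal(f0$sinuosity, 1)

  expect_error(window_features(w[1, ]), "at least 2")
})

test_that("speed and sinuosity are translation- and reflection-invariant", {
  set.seed(8)
  tr <- simulate_trajectory(sheep_movement_model(), arena_config(), 20, 50)
  f <- movement_features(tr)
  shifted <- trajectory(tr$time, tr$x + 0.4, tr$y + 1, phase = tr$phase,
                        rate = 50)
  reflected <- trajectory(tr$time, -tr$x, tr$y, phase = tr$phase, rate = 50)
  swapped <- trajectory(tr$time, tr$y, tr$x, phase = tr$phase, rate = 50)
  for (col in c("mean_speed", "sinuosity", "path_length")) {
    expect_equal(movement_features(shifted)[[col]], f[[col]], tolerance = 1e-9)
    expect_equal(movement_features(reflected)[[col]], f[[col]], tolerance = 1e-9)
  }
  # axis exchange swaps the lateral and longitudinal components
  fs <- movement_features(swapped)
  expect_equal(fs$lateral_speed, f$longitudinal_speed, tolerance = 1e-9)
  expect_equal(fs$longitudinal_speed, f$lateral_speed, tolerance = 1e-9)
})

test_that("AIC-selected mixtures recover planted two-mode structure", {
  p <- iso_two_modes(400, sep = 10, seed = 1)
  m <- fit_movement_classes(p$features, k_range = 1:6, seed = 1)
  expect_equal(m$n_classes, 2)
  expect_equal(unname(m$aic_curve[as.character(m$n_classes)]),
               min(m$aic_curve, na.rm = TRUE))
  tab <- table(p$labels, m$labels)
  expect_gte(sum(apply(tab, 1, max)) / 400, 0.99)
})

test_that("a single mode selects k = 1", {
  set.seed(2)
  X <- matrix(rnorm(300 * 5), 300, 5)
  f <- as.data.frame(X)
  names(f) <- c("mean_speed", "sinuosity", "path_length",
                "lateral_speed", "longitudinal_speed")
  m <- fit_movement_classes(f, k_range = 1:4, seed = 2)
  expect_equal(m$n_classes, 1)
})

test_that("degenerate feature matrices are rejected", {
  f <- data.frame(mean_speed = rep(1, 50), sinuosity = 1, path_length = 1,
                  lateral_speed = 1, longitudinal_speed = rnorm(50))
  expect_error(fit_movement_classes(f, k_range = 1:2), "degenerate")
  p <- iso_two_modes(10, seed = 3)
  expect_error(fit_movement_classes(p$features, k_range = 6:8),
               "too few windows")
})

test_that("semantic labels respect the quadrant structure", {
  p <- planted_feature_modes(600, c(0.4, 0.3, 0.2, 0.1), seed = 4)
  m <- fit_movement_classes(p$features, k_range = 2:6, seed = 4)
  occ <- semantic_occupancy(m)
  truth <- prop.table(table(factor(p$quadrants[p$labels],
                                   levels = names(occ))))
  expect_true(all(abs(occ - as.numeric(truth)) < 0.05))
})

test_that("class time rates are per-phase proportions summing to one", {
  p <- planted_feature_modes(200, c(0.5, 0.5), seed = 5)
  m <- fit_movement_classes(p$features, k_range = 2, seed = 5)
  phases <- rep(c("2", "3"), each = 100)
  rates <- class_time_rates(m, phases)
  expect_equal(unname(rowSums(rates)), c(1, 1), tolerance = 1e-9)
  expect_error(class_time_rates(m, phases[1:10]), "align")

  # all windows one class
  m1 <- m; m1$labels <- rep(1L, 200); m1$n_classes <- 2L
  r1 <- class_time_rates(m1, phases)
  expect_equal(unname(r1[, 1]), c(1, 1))
  expect_equal(unname(r1[, 2]), c(0, 0))

  # alternating two classes
  m2 <- m; m2$labels <- rep(c(1L, 2L), 100)
  expect_equal(unname(class_time_rates(m2, rep("2", 200))[1, ]), c(0.5, 0.5))
})

test_that("fast movement proportion uses only slow and fast classes", {
  m <- list(labels = c(1L, 2L, 1L, 2L, 3L, 3L),
            class_names = c("slow", "fast", "fast_tortuous"),
            n_classes = 3L)
  phases <- rep("2", 6)
  expect_equal(fast_movement_proportion(m, phases, "2"), 0.5)
  m2 <- list(labels = rep(1L, 4), class_names = "slow", n_classes = 1L)
  expect_equal(fast_movement_proportion(m2, rep("2", 4), "2"), 0)
  m3 <- list(labels = rep(1L, 4), class_names = "fast_tortuous",
             n_classes = 1L)
  expect_error(fast_movement_proportion(m3, rep("2", 4), "2"),
               "no slow or fast")

  # planted 3:1 fast:slow
  p <- planted_feature_modes(200, c(0.25, 0.75), seed = 6)
  mf <- fit_movement_classes(p$features, k_range = 2, seed = 6)
  planted_frac <- mean(p$labels == 2)
  expect_equal(fast_movement_proportion(mf, p$features$phase, "2"),
               planted_frac, tolerance = 0.02)
  expect_equal(planted_frac, 0.75, tolerance = 0.12)
})
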