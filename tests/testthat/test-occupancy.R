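test_that("the default arena partitions into 80 lamb-sized zones", {
  g <- build_grid(arena_config())
  expect_equal(g$n_cells, 80L)
  expect_equal(g$n_length, 16L)
  expect_equal(g$n_width, 5L)
  expect_equal(g$cell_length, 0.4375)
  expect_equal(g$cell_width, 0.40)

  g1 <- build_grid(arena_config(grid_partitions = c(1L, 1L)))
  expect_equal(g1$n_cells, 1L)
  expect_error(build_grid(arena_config(grid_partitions = c(0L, 5L))))
})

test_that("cell indexing is half-open, closed at the far edge", {
  g <- build_grid(arena_config())
  # arena corner (entrance side, left wall) is cell (0, 0)
  expect_equal(unlist(cell_index(g, -1, 0)),
               c(i_length = 0L, i_width = 0L, cell = 0L))
  # an internal boundary point belongs to the higher-index cell
  expect_equal(cell_index(g, -1 + 0.40, 0)$i_width, 1L)
  expect_equal(cell_index(g, -1, 0.4375)$i_length, 1L)
  # the far edges are closed (clamped into the last cell)
  expect_equal(cell_index(g, 1, 7)$cell, 79L)
})

test_that("dwell visits are maximal runs split at phase boundaries", {
  g <- build_grid(arena_config())
  tr <- scripted_trajectory(data.frame(x = 0.1, y = 2.05, dwell = 60),
                            rate = 50)
  dw <- dwell_times(tr, g)
  expect_equal(nrow(dw$visits), 1)
  expect_equal(dw$visits$duration, 60)

  # 3 cells x 0.3 s dwells: three visits of 0.3 s
  wp <- data.frame(x = c(-0.8, -0.8, -0.8), y = c(0.2, 1.2, 2.2), dwell = 0.3)
  dw3 <- dwell_times(scripted_trajectory(wp, rate = 50), g)
  expect_equal(nrow(dw3$visits), 3)
  expect_true(all(dw3$visits$duration == 0.3))

  # sample-by-sample cell alternation at 50 Hz: all visits 0.02 s
  n <- 100
  tr_alt <- trajectory((0:(n - 1)) / 50, rep(0, n),
                       rep(c(0.1, 0.8), n / 2), phase = "2", rate = 50)
  dwa <- dwell_times(tr_alt, g)
  expect_true(all(dwa$visits$duration == 0.02))

  # a run spanning a phase boundary is split at the boundary
  tms <- (0:99) / 50
  trp <- trajectory(tms, rep(0, 100), rep(1, 100),
                    phase = rep(c("2", "3"), each = 50), rate = 50)
  dwp <- dwell_times(trp, g)
  expect_equal(nrow(dwp$visits), 2)
  expect_equal(dwp$visits$phase, c("2", "3"))

  expect_error(dwell_times(trp[0, ], g), "empty")
})

test_that("heatmap score counts zones with supra-threshold visits", {
  g <- build_grid(arena_config())
  tr <- scripted_trajectory(data.frame(x = 0, y = 3, dwell = 60), rate = 50)
  expect_equal(heatmap_score(dwell_times(tr, g)), 1L)

  wp3 <- data.frame(x = rep(-0.8, 3), y = c(0.2, 1.2, 2.2), dwell = 0.3)
  expect_equal(heatmap_score(dwell_times(scripted_trajectory(wp3, 50), g)), 3L)

  wp_short <- data.frame(x = rep(-0.8, 3), y = c(0.2, 1.2, 2.2), dwell = 0.1)
  dw_short <- dwell_times(scripted_trajectory(wp_short, 50), g)
  expect_equal(heatmap_score(dw_short), 0L)
  # cumulative mode aggregates revisits
  wp_re <- data.frame(x = rep(-0.8, 4), y = c(0.2, 1.2, 0.2, 1.2), dwell = 0.15)
  dw_re <- dwell_times(scripted_trajectory(wp_re, 50), g)
  expect_equal(heatmap_score(dw_re), 0L)
  expect_equal(heatmap_score(dw_re, cumulative = TRUE), 2L)

  # bounded by the number of zones
  set.seed(3)
  tr_r <- simulate_trajectory(sheep_movement_model(), arena_config(), 60, 50)
  hs <- heatmap_score(dwell_times(tr_r, g))
  expect_true(hs >= 0 && hs <= 80)
})

test_that("area times tile the arena length and conserve time", {
  arena <- arena_config()
  tr <- scripted_trajectory(data.frame(x = 0, y = 6.5, dwell = 30), rate = 50)
  at <- area_times(tr, arena)
  expect_length(at, 7)
  expect_equal(unname(at["area7"]), 30)
  expect_equal(sum(at[-7]), 0)

  # uniform constant-speed sweep covers the sevenths nearly equally
  rate <- 50
  tms <- seq(0, 70 - 1 / rate, by = 1 / rate)
  tr_sweep <- trajectory(tms, rep(0, length(tms)), tms / 10, rate = rate)
  at_sweep <- area_times(tr_sweep, arena)
  expect_true(all(abs(at_sweep - 10) <= 10 * 0.01 + 1 / rate))
  expect_equal(sum(at_sweep), length(tms) / rate, tolerance = 1 / rate)
})

test_that("proximity score weights dwell towards the conspecific end", {
  arena <- arena_config()
  T_ <- 30
  near <- area_times(scripted_trajectory(
    data.frame(x = 0, y = 6.5, dwell = T_), 50), arena)
  expect_equal(proximity_score(near), 7 * T_)
  far <- area_times(scripted_trajectory(
    data.frame(x = 0, y = 0.5, dwell = T_), 50), arena)
  expect_equal(proximity_score(far), 1 * T_)

  # equal sevenths of 60 s score mean weight x duration
  eq <- rep(60 / 7, 7)
  expect_equal(proximity_score(eq), 4 * 60)

  expect_error(proximity_score(eq, weights = 1:6), "one weight per")
  expect_error(proximity_score(eq, weights = 7:1), "non-decreasing")

  # monotone: moving time towards a higher-weight area never decreases it
  set.seed(4)
  for (i in 1:20) {
    t0 <- runif(7)
    from <- sample(6, 1); to <- sample(from:7, 1)
    t1 <- t0; d <- t0[from] * 0.5
    t1[from] <- t1[from] - d; t1[to] <- t1[to] + d
    expect_gte(proximity_score(t1), proximity_score(t0))
  }
})

test_that("crossing rate counts boundary crossings exactly", {
  arena <- arena_config()
  still <- scripted_trajectory(data.frame(x = 0, y = 2.5, dwell = 5), 50)
  expect_equal(crossing_rate(still, arena), 0L)

  # monotone sweep from area 1 to area 7
  sweep7 <- scripted_trajectory(
    data.frame(x = 0, y = seq(0.5, 6.5, 1), dwell = 0.5), 50)
  expect_equal(crossing_rate(sweep7, arena), 6L)

  # one jump across all six boundaries also counts 6
  jump <- scripted_trajectory(
    data.frame(x = 0, y = c(0.5, 6.5), dwell = 0.5), 50)
  expect_equal(crossing_rate(jump, arena), 6L)

  # back-and-forth across one boundary n times
  n <- 9
  bf <- scripted_trajectory(
    data.frame(x = 0, y = rep(c(1.9, 2.1), length.out = n + 1), dwell = 0.1),
    50)
  expect_equal(crossing_rate(bf, arena), n)
})

test_that("infrared events reconstruct the crossing count exactly", {
  arena <- arena_config()
  still <- scripted_trajectory(data.frame(x = 0, y = 2.5, dwell = 5), 50)
  expect_equal(nrow(infrared_events(still, arena)), 0L)

  sweep7 <- scripted_trajectory(
    data.frame(x = 0, y = seq(0.5, 6.5, 1), dwell = 0.5), 50)
  ev <- infrared_events(sweep7, arena)
  expect_equal(ev$beam, 1:6)
  expect_true(all(ev$direction == 1))
  expect_true(!is.unsorted(ev$time))

  set.seed(5)
  tr <- simulate_trajectory(sheep_movement_model(), arena_config(), 60, 50)
  expect_equal(nrow(infrared_events(tr, arena)), crossing_rate(tr, arena))
})
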