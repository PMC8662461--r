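#' Planted Gaussian feature modes for class-recovery studies
#'
#' Draws window-feature vectors from known Gaussian modes placed in the four
#' semantic quadrants (slow / fast x plain / tortuous), with known
#' occupancies. Used to validate mixture-based class discovery: the true
#' per-window quadrant is returned alongside.
#'
#' @param n Number of windows.
#' @param occupancy Mode probabilities; its length (1 to 4) selects the first
#'   modes of the quadrant sequence slow, fast, fast_tortuous, slow_tortuous.
#' @param seed Optional seed.
#' @return A list: `features` (a `window_features`-shaped data.frame),
#'   `labels` (true mode index per window), `quadrants` (semantic name per
#'   mode).
#' @export
planted_feature_modes <- function(n, occupancy = c(0.513, 0.355, 0.102, 0.030),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(occupancy)
  stopifnot(k >= 1, k <= 4, all(occupancy > 0))
  centers <- matrix(c(0.05, 1.15, 0.05, 0.03, 0.03,   # slow
                      0.80, 1.10, 0.80, 0.40, 0.40,   # fast
                      0.80, 4.00, 0.80, 0.40, 0.40,   # fast tortuous
                      0.05, 4.50, 0.05, 0.03, 0.03),  # slow tortuous
                    4, 5, byrow = TRUE)
  sds <- matrix(c(0.010, 0.05, 0.010, 0.010, 0.010,
                  0.050, 0.05, 0.050, 0.030, 0.030,
                  0.050, 0.30, 0.050, 0.030, 0.030,
                  0.010, 0.30, 0.010, 0.010, 0.010),
                4, 5, byrow = TRUE)
  quadrants <- c("slow", "fast", "fast_tortuous", "slow_tortuous")[seq_len(k)]
  lab <- sample.int(k, n, replace = TRUE, prob = occupancy)
  X <- centers[lab, , drop = FALSE] +
    matrix(stats::rnorm(n * 5), n, 5) * sds[lab, , drop = FALSE]
  X[, 1] <- pmax(X[, 1], 0)          # speeds are non-negative
  X[, 2] <- pmax(X[, 2], 1)          # sinuosity >= 1
  f <- as.data.frame(X)
  names(f) <- c("mean_speed", "sinuosity", "path_length",
                "lateral_speed", "longitudinal_speed")
  f$window_start <- seq_len(n) - 1
  f$phase <- "2"
  class(f) <- c("window_features", "data.frame")
  list(features = f, labels = lab, quadrants = quadrants)
}

#' Occupancy of the semantic classes recovered by a class model
#'
#' Fraction of windows labelled slow / fast / fast_tortuous / slow_tortuous
#' after mixture fitting and semantic naming; components falling in the same
#' quadrant are pooled.
#'
#' @param model A `class_model`.
#' @return Named numeric vector over the four semantic classes (sums to 1).
#' @export
semantic_occupancy <- function(model) {
  labs <- model$class_names[model$labels]
  out <- setNames(numeric(4),
                  c("slow", "fast", "fast_tortuous", "slow_tortuous"))
  tab <- table(labs) / length(labs)
  out[names(tab)] <- tab
  out
}

#' Trajectory with a known number of planted movement changes
#'
#' A piecewise-constant-velocity track whose velocity switches at
#' `n_switches` times evenly spaced inside the central part of the recording
#' (clear of the wavelet boundary margins), alternating direction so the path
#' never reaches a wall (wall reflections would add unplanned movement
#' changes). Used to calibrate and validate wavelet transition counting.
#'
#' @param n_switches Number of planted velocity changes.
#' @param duration Duration in seconds (default 60, one phase).
#' @param rate Sampling rate (Hz).
#' @param arena An `arena_config`.
#' @param position_noise_sd Gaussian position jitter (m), default 5 mm.
#' @param seed Optional seed (jitter only; the switch structure is fixed).
#' @param phase Phase label (default "2").
#' @return A `sheep_trajectory` with attribute `switch_times`.
#' @export
planted_switch_trajectory <- function(n_switches, duration = 60, rate = 50,
                                      arena = arena_config(),
                                      position_noise_sd = 0.005,
                                      seed = NULL, phase = "2") {
  stopifnot(n_switches >= 1)
  sw <- seq(duration / 6, duration * 5 / 6, length.out = n_switches)
  sgn <- rep(c(1, -1), length.out = n_switches + 1)
  vel <- cbind(0.05 * sgn, 0.15 * sgn)
  tr <- piecewise_velocity_trajectory(sw, duration, rate, arena,
                                      velocities = vel,
                                      position_noise_sd = position_noise_sd,
                                      seed = seed,
                                      start = c(0, arena$length / 2),
                                      phase = phase)
  attr(tr, "switch_times") <- sw
  tr
}
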