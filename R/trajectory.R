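#' Construct a trajectory object
#'
#' A trajectory is a data.frame of time-stamped 2D positions in arena
#' coordinates (see [arena_config()] for the convention), with a phase label
#' per sample.
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param x,y Positions in metres (x across the width, y along the length).
#' @param phase Phase label per sample (character or factor); recycled.
#' @param source One of "ground_truth", "radar", "external".
#' @param rate Sampling rate in Hz; inferred from `time` when `NULL`.
#' @param extra Optional named list of extra per-sample columns (e.g.
#'   `valid`, `state`).
#' @return A data.frame of class `sheep_trajectory` with attributes `source`
#'   and `rate`.
#' @export
trajectory <- function(time, x, y, phase = "1", source = "ground_truth",
                       rate = NULL, extra = NULL) {
  n <- length(time)
  stopifnot(length(x) == n, length(y) == n, n >= 1)
  if (n > 1 && any(diff(time) <= 0))
    stop("trajectory times must be strictly increasing")
  if (is.null(rate)) {
    rate <- if (n > 1) 1 / stats::median(diff(time)) else NA_real_
  }
  out <- data.frame(time = time, x = x, y = y,
                    phase = as.character(rep_len(phase, n)),
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  structure(out, source = source, rate = rate,
            class = c("sheep_trajectory", "data.frame"))
}

#' Sampling rate of a trajectory (Hz)
#' @param traj A `sheep_trajectory`.
#' @return Rate in Hz.
#' @export
traj_rate <- function(traj) attr(traj, "rate")

#' Assign arena-test phase labels from sample times
#'
#' Phases 1..3 are delimited by the cumulative phase durations of the arena
#' configuration; samples beyond the protocol keep the last phase label.
#'
#' @param time Sample times in seconds (0 = test start).
#' @param arena An `arena_config`.
#' @return Character vector of phase labels.
#' @export
assign_phases <- function(time, arena) {
  edges <- cumsum(arena$phase_durations)
  idx <- findInterval(time, edges, left.open = FALSE) + 1L
  idx <- pmin(idx, length(edges))
  as.character(idx)
}

## Fold an unbounded coordinate into [lo, hi] by reflection (triangle wave);
## equivalent to specular reflection at the walls. In-range values are
## returned untouched (exact).
.reflect_fold <- function(p, lo, hi) {
  out <- which(p < lo | p > hi)
  if (length(out)) {
    w <- hi - lo
    r <- (p[out] - lo) %% (2 * w)
    p[out] <- lo + ifelse(r > w, 2 * w - r, r)
  }
  p
}

#' Simulate a Markov-switching correlated random walk in the arena
#'
#' Draws a latent state sequence from the model's transition matrix, then a
#' per-sample speed (truncated at zero) and heading random walk per state,
#' and integrates positions with reflective arena boundaries.
#'
#' @param model A [trajectory_model()].
#' @param arena An [arena_config()].
#' @param duration Duration in seconds; the trajectory has
#'   `ceiling(duration * rate)` samples.
#' @param rate Sampling rate in Hz (default 50, the radar frame rate).
#' @param seed Optional integer seed.
#' @param start Optional starting position `c(x, y)`; default: centre of the
#'   entrance end, `(0, 0.5)`.
#' @param start_state Optional starting latent state index; default drawn
#'   from the chain's stationary distribution.
#' @param t0 Time of the first sample (seconds; default 0).
#' @param phase Phase labels: `NULL` assigns labels from `arena` phase
#'   durations, otherwise recycled over samples.
#' @return A `sheep_trajectory` with a per-sample latent `state` column
#'   (state names) for recovery tests.
#' @export
simulate_trajectory <- function(model, arena, duration, rate = 50,
                                seed = NULL, start = NULL, start_state = NULL,
                                t0 = 0, phase = NULL) {
  stopifnot(inherits(model, "trajectory_model"), inherits(arena, "arena_config"),
            duration > 0, rate > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration * rate)
  dt <- 1 / rate
  P <- model$transition_matrix
  k <- nrow(P)
  pi0 <- stationary_distribution(P)
  s <- integer(n)
  s[1] <- if (is.null(start_state)) sample.int(k, 1, prob = pi0) else start_state
  if (n > 1) for (i in 2:n) s[i] <- sample.int(k, 1, prob = P[s[i - 1], ])

  st <- model$states
  speed <- pmax(0, stats::rnorm(n, st$speed_mean[s], st$speed_sd[s]))
  dhead <- stats::rnorm(n, 0, st$turn_sd[s] * sqrt(dt))
  heading <- stats::runif(1, 0, 2 * pi) + cumsum(dhead)
  if (is.null(start)) start <- c(0, 0.5)
  xr <- start[1] + cumsum(c(0, (speed * dt * cos(heading))[-n]))
  yr <- start[2] + cumsum(c(0, (speed * dt * sin(heading))[-n]))
  x <- .reflect_fold(xr, -arena$width / 2, arena$width / 2)
  y <- .reflect_fold(yr, 0, arena$length)
  time <- t0 + (seq_len(n) - 1) * dt
  ph <- if (is.null(phase)) assign_phases(time, arena) else phase
  trajectory(time, x, y, phase = ph, source = "ground_truth", rate = rate,
             extra = list(state = st$name[s]))
}

#' Deterministic scripted trajectory through waypoints
#'
#' Holds each waypoint for its dwell duration (positions jump between
#' waypoints at the sample following the dwell). Used to build fixtures with
#' exactly known occupancy, crossing and dwell structure.
#'
#' @param waypoints A data.frame with columns `x`, `y` and `dwell` (seconds).
#' @param rate Sampling rate in Hz.
#' @param arena Optional `arena_config` used to validate that waypoints are
#'   inside the arena and to assign phases.
#' @param phase Phase label(s); recycled per waypoint. Ignored when `NULL`
#'   and `arena` is given (phases assigned from time).
#' @param t0 Time of the first sample.
#' @return A `sheep_trajectory`.
#' @export
scripted_trajectory <- function(waypoints, rate = 50, arena = NULL,
                                phase = NULL, t0 = 0) {
  stopifnot(is.data.frame(waypoints),
            all(c("x", "y", "dwell") %in% names(waypoints)))
  if (nrow(waypoints) == 0) stop("waypoint list is empty")
  if (!is.null(arena)) {
    ok <- waypoints$x >= -arena$width / 2 & waypoints$x <= arena$width / 2 &
      waypoints$y >= 0 & waypoints$y <= arena$length
    if (!all(ok)) stop("waypoints outside the arena")
  }
  reps <- pmax(1L, as.integer(round(waypoints$dwell * rate)))
  x <- rep(waypoints$x, reps)
  y <- rep(waypoints$y, reps)
  n <- length(x)
  time <- t0 + (seq_len(n) - 1) / rate
  ph <- if (!is.null(phase)) rep(rep_len(phase, nrow(waypoints)), reps)
        else if (!is.null(arena)) assign_phases(time, arena) else "1"
  trajectory(time, x, y, phase = ph, source = "ground_truth", rate = rate)
}

#' Piecewise-constant-velocity trajectory with planted switch times
#'
#' Moves with a constant velocity vector between switch times; at each switch
#' a new velocity is drawn (or taken from `velocities`). Positions reflect at
#' the arena walls. Used to plant a known number of movement changes for
#' wavelet transition-count calibration.
#'
#' @param switch_times Times (s) of the velocity changes, strictly inside
#'   `(0, duration)`.
#' @param duration Total duration in seconds.
#' @param rate Sampling rate (Hz).
#' @param arena An `arena_config`.
#' @param velocities Optional (k+1) x 2 matrix of velocity vectors (m/s) per
#'   segment; default alternates slow and fast segments along both axes.
#' @param position_noise_sd Isotropic Gaussian position jitter (m) added to
#'   every sample (default 0: exact piecewise-linear positions).
#' @param seed Optional seed (used for default velocities and jitter).
#' @param start Starting position, default arena centre.
#' @param phase Phase label for all samples (default "2").
#' @return A `sheep_trajectory`.
#' @export
piecewise_velocity_trajectory <- function(switch_times, duration, rate = 50,
                                          arena = arena_config(),
                                          velocities = NULL,
                                          position_noise_sd = 0,
                                          seed = NULL,
                                          start = NULL, phase = "2") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(switch_times > 0), all(switch_times < duration),
            !is.unsorted(switch_times, strictly = TRUE))
  n_seg <- length(switch_times) + 1L
  if (is.null(velocities)) {
    sp <- rep(c(0.15, 0.8), length.out = n_seg)
    ang <- stats::runif(n_seg, 0, 2 * pi)
    velocities <- cbind(sp * cos(ang), sp * sin(ang))
  }
  stopifnot(nrow(velocities) == n_seg)
  n <- ceiling(duration * rate)
  dt <- 1 / rate
  time <- (seq_len(n) - 1) * dt
  seg <- findInterval(time, switch_times) + 1L
  if (is.null(start)) start <- c(0, arena$length / 2)
  vx <- velocities[seg, 1]; vy <- velocities[seg, 2]
  xr <- start[1] + cumsum(c(0, (vx * dt)[-n]))
  yr <- start[2] + cumsum(c(0, (vy * dt)[-n]))
  if (position_noise_sd > 0) {
    xr <- xr + stats::rnorm(n, 0, position_noise_sd)
    yr <- yr + stats::rnorm(n, 0, position_noise_sd)
  }
  x <- .reflect_fold(xr, -arena$width / 2, arena$width / 2)
  y <- .reflect_fold(yr, 0, arena$length)
  trajectory(time, x, y, phase = phase, source = "ground_truth", rate = rate)
}
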