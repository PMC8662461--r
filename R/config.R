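#' Arena configuration
#'
#' Geometry and protocol of the standard arena (pen) test. The arena is a
#' rectangular pen with the radar placed at the entrance end; three
#' conspecifics stand behind a grid barrier at the far end. The test runs in
#' three phases (exploration with visual contact, social isolation behind an
#' opaque panel, conspecifics visible again with a motionless human present).
#'
#' Coordinate convention: origin at the radar, `y` along the arena length
#' (0 at the radar end, increasing towards the conspecifics), `x` across the
#' width, centred on the radar boresight (so `x` spans `[-width/2, width/2]`).
#' Azimuth angles are measured from boresight in degrees, positive towards
#' positive `x`.
#'
#' @param length Arena length in metres (default 7).
#' @param width Arena width in metres (default 2).
#' @param phase_durations Durations in seconds of the three test phases
#'   (default 15, 60, 60).
#' @param n_virtual_areas Number of 1-m virtual areas along the length used by
#'   the infrared-cell instrumentation (default 7).
#' @param grid_partitions Integer pair: number of occupancy-grid partitions
#'   along the length and across the width (default 16 and 5, i.e. 80 zones).
#' @param radar_pose Position of the radar origin, a numeric `c(x, y)`;
#'   the boresight heading is fixed along +y.
#'
#' @return An object of class `arena_config`.
#' @export
#' @examples
#' arena <- arena_config()
#' arena$length
arena_config <- function(length = 7, width = 2,
                         phase_durations = c(15, 60, 60),
                         n_virtual_areas = 7L,
                         grid_partitions = c(16L, 5L),
                         radar_pose = c(x = 0, y = 0)) {
  stopifnot(length > 0, width > 0, all(phase_durations > 0))
  n_virtual_areas <- as.integer(n_virtual_areas)
  grid_partitions <- as.integer(grid_partitions)
  if (n_virtual_areas * 1 > length + 1e-9)
    stop("n_virtual_areas 1-m areas do not fit in the arena length")
  if (any(grid_partitions < 1L))
    stop("grid_partitions must be positive")
  structure(list(
    length = length, width = width,
    phase_durations = phase_durations,
    n_virtual_areas = n_virtual_areas,
    grid_partitions = grid_partitions,
    radar_pose = radar_pose
  ), class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("Arena: %.1f m x %.1f m, phases %s s, %d virtual areas, %d x %d grid\n",
              x$width, x$length, paste(x$phase_durations, collapse = "/"),
              x$n_virtual_areas, x$grid_partitions[1], x$grid_partitions[2]))
  invisible(x)
}

#' Speed of light (m/s)
#' @keywords internal
.C_LIGHT <- 299792458

#' FMCW radar configuration
#'
#' Parameters of the frequency-modulated continuous-wave radar. The defaults
#' are the indoor unit: 77 GHz carrier, 3 GHz modulation bandwidth, 256 us
#' ramp, a 4 x 8 MIMO antenna array (32 virtual channels at half-wavelength
#' spacing), 50 degree field of view and 100 mW transmitted power. The outdoor
#' variant uses a 24 GHz carrier with 800 MHz bandwidth.
#'
#' @param carrier_frequency Carrier frequency in Hz.
#' @param bandwidth Modulation bandwidth in Hz; sets the range resolution
#'   c/(2B).
#' @param ramp_time Chirp (up-ramp) duration in seconds.
#' @param frame_rate Measurement rate in frames per second (default 50).
#' @param n_tx,n_rx Number of transmitting / receiving linear arrays; the
#'   virtual array has `n_tx * n_rx` channels.
#' @param element_spacing Virtual-array element spacing as a fraction of the
#'   carrier wavelength (default 0.5).
#' @param transmitted_power Transmitted power in watts.
#' @param field_of_view Azimuth field of view in degrees.
#' @param noise_sigma Standard deviation of the complex receiver noise, in
#'   linear amplitude units.
#' @param n_range_bins Number of fast-time samples per chirp (= range bins).
#' @param n_angle_bins Number of angle bins after zero-padded beamforming.
#'
#' @return An object of class `radar_config` with derived fields
#'   `wavelength`, `n_channels`, `range_bin_m` (range-bin width in metres)
#'   and `u_bin` (angle-bin width in sine space).
#' @export
radar_config <- function(carrier_frequency = 77e9, bandwidth = 3e9,
                         ramp_time = 256e-6, frame_rate = 50,
                         n_tx = 4L, n_rx = 8L, element_spacing = 0.5,
                         transmitted_power = 0.1, field_of_view = 50,
                         noise_sigma = 0.05,
                         n_range_bins = 256L, n_angle_bins = 64L) {
  stopifnot(carrier_frequency > 0, bandwidth > 0, ramp_time > 0,
            frame_rate > 0, element_spacing > 0, noise_sigma >= 0)
  if (bandwidth >= carrier_frequency)
    stop("bandwidth must be smaller than the carrier frequency")
  n_tx <- as.integer(n_tx); n_rx <- as.integer(n_rx)
  if (n_tx * n_rx < 1L) stop("need at least one virtual channel")
  n_range_bins <- as.integer(n_range_bins)
  n_angle_bins <- as.integer(n_angle_bins)
  if (n_angle_bins < n_tx * n_rx)
    stop("n_angle_bins must be at least the virtual channel count")
  structure(list(
    carrier_frequency = carrier_frequency, bandwidth = bandwidth,
    ramp_time = ramp_time, frame_rate = frame_rate,
    n_tx = n_tx, n_rx = n_rx, element_spacing = element_spacing,
    transmitted_power = transmitted_power, field_of_view = field_of_view,
    noise_sigma = noise_sigma,
    n_range_bins = n_range_bins, n_angle_bins = n_angle_bins,
    wavelength = .C_LIGHT / carrier_frequency,
    n_channels = n_tx * n_rx,
    range_bin_m = .C_LIGHT / (2 * bandwidth),
    u_bin = 1 / (n_angle_bins * element_spacing)
  ), class = "radar_config")
}

#' The outdoor radar variant (24 GHz, 800 MHz bandwidth, 1 ms ramp)
#' @param ... overrides passed to [radar_config()].
#' @return A `radar_config`.
#' @export
radar_config_outdoor <- function(...) {
  args <- utils::modifyList(
    list(carrier_frequency = 24e9, bandwidth = 800e6, ramp_time = 1e-3,
         n_tx = 1L, n_rx = 2L, field_of_view = 58),
    list(...))
  do.call(radar_config, args)
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf("FMCW radar: %.0f GHz, B = %.2f GHz (dr = %.3f m), %d x %d array, %g fps\n",
              x$carrier_frequency / 1e9, x$bandwidth / 1e9, x$range_bin_m,
              x$n_tx, x$n_rx, x$frame_rate))
  invisible(x)
}

#' Range-bin centres of a radar configuration (metres)
#' @param radar A `radar_config`.
#' @return Numeric vector of length `n_range_bins` (0-based bins; bin k is
#'   centred at `k * range_bin_m`).
#' @export
range_bins <- function(radar) {
  (seq_len(radar$n_range_bins) - 1) * radar$range_bin_m
}

#' Angle-bin centres in sine space and degrees
#'
#' Beamforming bins are uniform in `u = sin(azimuth)`; the grid spans the
#' unambiguous interval of the virtual array, `[-1, 1)` at half-wavelength
#' element spacing.
#'
#' @param radar A `radar_config`.
#' @return A list with `u` (sine of azimuth, uniform grid) and `azimuth_deg`.
#' @export
angle_bins <- function(radar) {
  n <- radar$n_angle_bins
  u <- (seq_len(n) - 1 - n %/% 2) / (n * radar$element_spacing)
  list(u = u, azimuth_deg = asin(pmin(1, pmax(-1, u))) * 180 / pi)
}

#' Latent movement-mode model for trajectory simulation
#'
#' A discrete-time Markov-switching correlated random walk. Each latent state
#' has a per-step speed distribution (truncated normal, m/s) and a turning
#' volatility; the heading performs a random walk with per-step standard
#' deviation `turn_sd * sqrt(dt)` (so `turn_sd` is in rad per sqrt(s):
#' small values give straight, persistent paths, large values tortuous ones).
#' States switch per sample according to a row-stochastic transition matrix.
#'
#' @param states A data.frame with columns `name`, `speed_mean`, `speed_sd`
#'   (m/s) and `turn_sd` (rad / sqrt(s)).
#' @param transition_matrix Row-stochastic square matrix, one row per state.
#' @return An object of class `trajectory_model`.
#' @seealso [sheep_movement_model()] for the default four-mode model.
#' @export
trajectory_model <- function(states, transition_matrix) {
  stopifnot(is.data.frame(states),
            all(c("name", "speed_mean", "speed_sd", "turn_sd") %in% names(states)))
  k <- nrow(states)
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(k, k)))
    stop("transition matrix must be ", k, " x ", k)
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stop("transition matrix rows must be non-negative and sum to 1")
  if (any(states$speed_mean < 0) || any(states$speed_sd < 0) ||
      any(states$turn_sd < 0))
    stop("speeds and turning volatilities must be non-negative")
  structure(list(states = states, transition_matrix = transition_matrix),
            class = "trajectory_model")
}

#' Default four-mode sheep movement model
#'
#' Four latent movement modes mirroring the behavioural classes typically
#' recovered in the arena test: slow, fast, fast tortuous and slow tortuous
#' (slow ~ 0.05 m/s, fast ~ 0.8 m/s; tortuous modes have high turning
#' volatility). The transition matrix is sticky with stationary distribution
#' `stationary` (default weighted towards slow and fast movement, with the
#' tortuous modes rare).
#'
#' @param stationary Stationary distribution over the four modes.
#' @param stickiness Per-sample probability of re-drawing the current state
#'   from `stationary` is `1 - stickiness`; at 50 Hz the default 0.98 gives a
#'   mean mode dwell of about one second.
#' @return A `trajectory_model`.
#' @export
sheep_movement_model <- function(stationary = c(0.50, 0.36, 0.10, 0.04),
                                 stickiness = 0.98) {
  stopifnot(length(stationary) == 4, all(stationary > 0),
            stickiness >= 0, stickiness < 1)
  stationary <- stationary / sum(stationary)
  states <- data.frame(
    name = c("slow", "fast", "fast_tortuous", "slow_tortuous"),
    speed_mean = c(0.05, 0.80, 0.80, 0.05),
    speed_sd = c(0.04, 0.20, 0.20, 0.04),
    turn_sd = c(1.0, 0.5, 8.0, 8.0),
    stringsAsFactors = FALSE)
  P <- stickiness * diag(4) +
    (1 - stickiness) * matrix(stationary, 4, 4, byrow = TRUE)
  trajectory_model(states, P)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to one.
#'
#' @param P Row-stochastic square matrix.
#' @return Numeric stationary distribution.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
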