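#' Theoretical range resolution of an FMCW radar
#'
#' Closed form `c / (2 B)`: 5 cm at 3 GHz modulation bandwidth, 18.7 cm at
#' 800 MHz.
#'
#' @param bandwidth Modulation bandwidth in Hz.
#' @return Range resolution in metres.
#' @export
#' @examples
#' range_resolution(3e9) # 0.05 m
range_resolution <- function(bandwidth) {
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  .C_LIGHT / (2 * bandwidth)
}

#' Free-space attenuation gain from lowering the carrier frequency
#'
#' At fixed transmitted power, free-space path loss scales with the square of
#' the carrier frequency, so moving from `f_high` to `f_low` gains
#' `20 log10(f_high / f_low)` dB of link budget: 10.13 dB from 77 GHz down
#' to 24 GHz.
#'
#' @param f_high,f_low Carrier frequencies in Hz.
#' @return Gain in dB.
#' @export
#' @examples
#' free_space_gain(77e9, 24e9) # 10.13 dB
free_space_gain <- function(f_high, f_low) {
  if (any(f_high <= 0) || any(f_low <= 0)) stop("frequencies must be positive")
  20 * log10(f_high / f_low)
}

.hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Convert a raw beat-signal frame to a range-azimuth map
#'
#' Windowed 2D discrete Fourier transform: along fast time (range; beat
#' frequency `f_b` maps to range `f_b c T_ramp / (2 B)`, so FFT bin k is
#' centred at `k * c/(2B)`) and across the virtual channels (angle; spatial
#' frequency maps to `u = sin(azimuth)`). A Hann window is applied on both
#' axes and the angle axis is zero-padded to `n_angle_bins`. The magnitude is
#' normalized so a unit-amplitude on-grid reflector peaks near 1.
#'
#' @param raw A `radar_raw_frame` (complex matrix, samples x channels) from
#'   [synthesize_beat_signal()].
#' @param radar The matching `radar_config`.
#' @param window Window name for both axes: "hann" or "rectangular".
#' @return A `range_azimuth_frame`.
#' @export
frame_to_map <- function(raw, radar = attr(raw, "radar"), window = "hann") {
  N <- radar$n_range_bins
  M <- radar$n_channels
  if (!is.matrix(raw) || nrow(raw) != N || ncol(raw) != M)
    stop("raw frame must be ", N, " samples x ", M, " channels")
  window <- match.arg(window, c("hann", "rectangular"))
  wN <- if (window == "hann") .hann(N) else rep(1, N)
  wM <- if (window == "hann") .hann(M) else rep(1, M)
  w <- unclass(raw) * (wN %o% wM)
  rng <- stats::mvfft(w)                      # fast-time FFT: rows = range bins
  nf <- radar$n_angle_bins
  pad <- matrix(0 + 0i, N, nf)
  pad[, seq_len(M)] <- rng
  ang <- t(stats::mvfft(t(pad)))              # channel FFT: cols = u bins
  shift <- c((nf %/% 2 + 1):nf, 1:(nf %/% 2)) # fftshift so u is ascending
  vals <- Mod(ang[, shift]) / (sum(wN) * sum(wM))
  range_azimuth_frame(vals, radar, timestamp = attr(raw, "timestamp") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## coerce list of frames / 3D array to 3D array [frame, range, angle]
.frame_array <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3) return(frames)
  if (inherits(frames, "range_azimuth_frame")) frames <- list(frames)
  vals <- lapply(frames, function(f) if (inherits(f, "range_azimuth_frame")) f$values else f)
  d <- dim(vals[[1]])
  arr <- array(NA_real_, c(length(vals), d[1], d[2]))
  for (i in seq_along(vals)) arr[i, , ] <- vals[[i]]
  arr
}

#' Estimate per-cell background (clutter) statistics
#'
#' From frames recorded in the absence of the animal, computes the per-cell
#' time mean and sample standard deviation of the amplitude. These are the
#' `mean(r, theta)` and `std(r, theta)` used by the clutter-normalization
#' statistic.
#'
#' @param frames A list of `range_azimuth_frame`s (or a 3D array,
#'   frame x range x angle) with the animal absent; at least 2 frames.
#' @return An object of class `clutter_stats` with matrices `mean` and `std`
#'   and the frame count `n_frames`.
#' @export
estimate_clutter <- function(frames) {
  arr <- .frame_array(frames)
  n <- dim(arr)[1]
  if (n < 2) stop("clutter estimation needs at least 2 background frames")
  mu <- apply(arr, c(2, 3), mean)
  sdv <- apply(arr, c(2, 3), stats::sd)
  structure(list(mean = mu, std = sdv, n_frames = n), class = "clutter_stats")
}

#' Clutter-normalize a frame
#'
#' The detection statistic is the per-cell standardized amplitude
#' `D(t, r, theta) = (S(t, r, theta) - mean(r, theta)) / std(r, theta)`,
#' where mean and std are the background statistics estimated with the animal
#' absent. Cells with (near-)zero background variance are guarded by `eps`.
#'
#' @param frame A `range_azimuth_frame` with the animal present.
#' @param clutter A `clutter_stats` on the same grid.
#' @param eps Lower bound on the divisor, in amplitude units.
#' @return An object of class `normalized_frame` (same grid, values are D).
#' @export
normalize_frame <- function(frame, clutter, eps = 1e-12) {
  stopifnot(inherits(frame, "range_azimuth_frame"),
            inherits(clutter, "clutter_stats"))
  if (!all(dim(frame$values) == dim(clutter$mean)))
    stop("frame and clutter grids differ in shape")
  d <- (frame$values - clutter$mean) / pmax(clutter$std, eps)
  out <- frame
  out$values <- d
  class(out) <- c("normalized_frame", "range_azimuth_frame")
  out
}

#' Detect the target in a normalized frame
#'
#' Single-target rule: the global argmax cell of D is a detection if its
#' value reaches `threshold`; otherwise the frame yields no valid fix. Exact
#' ties are broken towards the smaller range bin, then the smaller angle bin.
#' The position is refined to sub-bin accuracy by 3-point parabolic
#' interpolation along the range axis and along the angle (sine-space) axis;
#' refinement is skipped at grid edges.
#'
#' @param frame A `normalized_frame` (or any frame-like object; detection on
#'   raw amplitude maps is useful for noiseless fixtures).
#' @param threshold Detection threshold on D (default 5).
#' @return An object of class `radar_detection`: list with `timestamp`,
#'   `range` (m), `azimuth_deg`, `u`, `score` (peak D) and `valid`.
#' @export
detect_target <- function(frame, threshold = 5) {
  stopifnot(threshold > 0)
  v <- frame$values
  mx <- max(v)
  det <- list(timestamp = frame$timestamp, range = NA_real_,
              azimuth_deg = NA_real_, u = NA_real_, score = mx,
              valid = mx >= threshold)
  class(det) <- "radar_detection"
  if (!det$valid) return(det)
  cand <- which(v == mx, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  i <- cand[1, 1]; j <- cand[1, 2]

  para <- function(a, b, c) {
    den <- a - 2 * b + c
    if (!is.finite(den) || den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (a - c) / den))
  }
  dr <- if (i > 1 && i < nrow(v)) para(v[i - 1, j], v[i, j], v[i + 1, j]) else 0
  du <- if (j > 1 && j < ncol(v)) para(v[i, j - 1], v[i, j], v[i, j + 1]) else 0
  rbw <- frame$range_m[2] - frame$range_m[1]
  ubw <- frame$u[2] - frame$u[1]
  det$range <- frame$range_m[i] + dr * rbw
  det$u <- max(-1, min(1, frame$u[j] + du * ubw))
  det$azimuth_deg <- asin(det$u) * 180 / pi
  det
}

#' Assemble a 2D trajectory from per-frame detections
#'
#' Converts polar detections to arena Cartesian coordinates using the radar
#' pose (radar at origin, boresight along +y: `x = r sin(theta)`,
#' `y = r cos(theta)`). Gaps of invalid detections are filled by
#' constant-velocity linear interpolation between the flanking valid fixes;
#' leading/trailing gaps hold the nearest valid fix. Fixes outside the arena
#' are clamped to its bounds and flagged in the `clamped` column.
#'
#' @param detections A data.frame with columns `time`, `range`,
#'   `azimuth_deg`, `valid`, or a list of `radar_detection`s plus frame times.
#' @param rate Frame rate in Hz (used as the trajectory sampling rate).
#' @param arena An `arena_config` (bounds, phases, radar pose).
#' @return A `sheep_trajectory` (source "radar") with `valid` and `clamped`
#'   columns.
#' @export
assemble_track <- function(detections, rate, arena = arena_config()) {
  if (!is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(detections, function(d)
      data.frame(time = d$timestamp, range = d$range,
                 azimuth_deg = d$azimuth_deg, valid = d$valid)))
  }
  stopifnot(all(c("time", "range", "azimuth_deg", "valid") %in% names(detections)))
  if (is.unsorted(detections$time, strictly = TRUE))
    stop("detections must be strictly time-ordered")
  ok <- detections$valid & is.finite(detections$range)
  if (!any(ok)) stop("no valid detections to assemble a track from")
  th <- detections$azimuth_deg * pi / 180
  x0 <- detections$range * sin(th) + arena$radar_pose[["x"]]
  y0 <- detections$range * cos(th) + arena$radar_pose[["y"]]
  tms <- detections$time
  x <- if (sum(ok) == 1) rep(x0[ok], length(tms))
       else stats::approx(tms[ok], x0[ok], xout = tms, rule = 2)$y
  y <- if (sum(ok) == 1) rep(y0[ok], length(tms))
       else stats::approx(tms[ok], y0[ok], xout = tms, rule = 2)$y
  xc <- pmin(pmax(x, -arena$width / 2), arena$width / 2)
  yc <- pmin(pmax(y, 0), arena$length)
  clamped <- (xc != x) | (yc != y)
  trajectory(tms, xc, yc, phase = assign_phases(tms, arena),
             source = "radar", rate = rate,
             extra = list(valid = ok, clamped = clamped))
}
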