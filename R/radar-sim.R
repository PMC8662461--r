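#' Static clutter scene
#'
#' The clutter is the set of static reflectors in the scene (pen walls,
#' fixtures) whose echoes mask the animal's. Amplitudes are time-invariant:
#' the clutter-normalization statistic assumes a stationary background.
#'
#' @param range Reflector ranges in metres (>= 0).
#' @param azimuth_deg Reflector azimuths in degrees from boresight.
#' @param amplitude Linear echo amplitudes.
#' @return An object of class `clutter_scene` (data.frame).
#' @export
clutter_scene <- function(range = numeric(), azimuth_deg = numeric(),
                          amplitude = numeric()) {
  stopifnot(length(range) == length(azimuth_deg),
            length(range) == length(amplitude))
  if (any(range < 0)) stop("reflector ranges must be non-negative")
  structure(data.frame(range = range, azimuth_deg = azimuth_deg,
                       amplitude = amplitude),
            class = c("clutter_scene", "data.frame"))
}

#' Wall-like clutter scene for the default arena
#'
#' Lines of point scatterers along the two side walls and the far (grid
#' barrier) end of the pen, as seen from the radar at the entrance end.
#'
#' @param arena An `arena_config`.
#' @param spacing Scatterer spacing along the walls (m).
#' @param amplitude Per-scatterer amplitude.
#' @return A `clutter_scene`.
#' @export
arena_clutter_scene <- function(arena = arena_config(), spacing = 0.25,
                                amplitude = 2) {
  hw <- arena$width / 2
  ys <- seq(0.5, arena$length, by = spacing)
  xs <- seq(-hw, hw, by = spacing)
  pts <- rbind(cbind(-hw, ys), cbind(hw, ys), cbind(xs, arena$length))
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  clutter_scene(range = r,
                azimuth_deg = asin(pts[, 1] / r) * 180 / pi,
                amplitude = rep(amplitude, length(r)))
}

## (range m, azimuth deg, amplitude) rows for scene plus optional target
.reflector_table <- function(position, scene, target_amplitude) {
  tab <- as.data.frame(scene)[, c("range", "azimuth_deg", "amplitude")]
  if (!is.null(position)) {
    if (position[2] <= 0) stop("target is behind the radar plane")
    r <- sqrt(position[1]^2 + position[2]^2)
    th <- asin(position[1] / r) * 180 / pi
    tab <- rbind(tab, data.frame(range = r, azimuth_deg = th,
                                 amplitude = target_amplitude))
  }
  tab
}

#' Range-azimuth frame constructor
#'
#' One radar measurement: non-negative amplitudes on a polar (range bin x
#' angle bin) grid. Angle bins are uniform in sine space (`u = sin(azimuth)`),
#' the natural beamforming grid of a uniform linear array.
#'
#' @param values Numeric matrix, `n_range_bins` x `n_angle_bins`.
#' @param radar The `radar_config` describing the grid.
#' @param timestamp Frame time in seconds.
#' @return An object of class `range_azimuth_frame`.
#' @export
range_azimuth_frame <- function(values, radar, timestamp = 0) {
  stopifnot(is.matrix(values),
            nrow(values) == radar$n_range_bins,
            ncol(values) == radar$n_angle_bins,
            all(is.finite(values)))
  ab <- angle_bins(radar)
  structure(list(values = values, timestamp = timestamp,
                 range_m = range_bins(radar), u = ab$u,
                 azimuth_deg = ab$azimuth_deg, radar = radar),
            class = "range_azimuth_frame")
}

#' @export
print.range_azimuth_frame <- function(x, ...) {
  cat(sprintf("Range-azimuth frame t = %.3f s: %d range x %d angle bins, max %.3g\n",
              x$timestamp, nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Synthesize a raw FMCW beat-signal frame
#'
#' Standard FMCW point-reflector model. Each reflector at range r and azimuth
#' theta contributes a complex fast-time tone at the beat frequency
#' `f_b = 2 B r / (c T_ramp)` with an inter-channel phase progression
#' `2 pi d sin(theta) / lambda` across the virtual array (`n_tx * n_rx`
#' channels at spacing `d = element_spacing * lambda`). Circular Gaussian
#' receiver noise with standard deviation `noise_sigma` is added per sample.
#'
#' @param position Target position `c(x, y)` in arena coordinates, or `NULL`
#'   for a background (clutter-only) frame.
#' @param scene A `clutter_scene` (may be empty).
#' @param radar A `radar_config`.
#' @param seed Optional seed for the noise.
#' @param target_amplitude Echo amplitude of the target.
#' @param timestamp Frame time (s).
#' @return A complex matrix (`n_range_bins` fast-time samples x `n_channels`)
#'   of class `radar_raw_frame`.
#' @export
synthesize_beat_signal <- function(position, scene = clutter_scene(),
                                   radar = radar_config(), seed = NULL,
                                   target_amplitude = 10, timestamp = 0) {
  if (!is.null(seed)) set.seed(seed)
  tab <- .reflector_table(position, scene, target_amplitude)
  N <- radar$n_range_bins
  M <- radar$n_channels
  fs <- N / radar$ramp_time
  tt <- (seq_len(N) - 1) / fs
  mm <- seq_len(M) - 1
  sig <- matrix(0 + 0i, N, M)
  for (i in seq_len(nrow(tab))) {
    fb <- 2 * radar$bandwidth * tab$range[i] / (.C_LIGHT * radar$ramp_time)
    u <- sin(tab$azimuth_deg[i] * pi / 180)
    tone <- tab$amplitude[i] * exp(2i * pi * fb * tt)
    steer <- exp(2i * pi * radar$element_spacing * u * mm)
    sig <- sig + tone %o% steer
  }
  if (radar$noise_sigma > 0) {
    sig <- sig + matrix(complex(real = stats::rnorm(N * M, 0, radar$noise_sigma / sqrt(2)),
                                imaginary = stats::rnorm(N * M, 0, radar$noise_sigma / sqrt(2))),
                        N, M)
  }
  structure(sig, class = c("radar_raw_frame", class(sig)),
            timestamp = timestamp, radar = radar)
}

#' Synthesize a range-azimuth map directly (map level)
#'
#' Shortcut bypassing the beat-signal synthesis and DSP: each reflector
#' contributes a separable Gaussian point-spread (FWHM one range bin by one
#' angle bin) centred on its (range, sin azimuth) coordinates, and circular
#' Gaussian noise is added in the complex domain before taking magnitudes,
#' so amplitudes stay non-negative (background cells are Rayleigh).
#'
#' @inheritParams synthesize_beat_signal
#' @return A `range_azimuth_frame`.
#' @export
synthesize_map <- function(position, scene = clutter_scene(),
                           radar = radar_config(), seed = NULL,
                           target_amplitude = 10, timestamp = 0) {
  if (!is.null(seed)) set.seed(seed)
  tab <- .reflector_table(position, scene, target_amplitude)
  rg <- range_bins(radar)
  ug <- angle_bins(radar)$u
  sd_r <- radar$range_bin_m / 2.355
  sd_u <- radar$u_bin / 2.355
  field <- matrix(0, radar$n_range_bins, radar$n_angle_bins)
  for (i in seq_len(nrow(tab))) {
    u0 <- sin(tab$azimuth_deg[i] * pi / 180)
    kr <- exp(-(rg - tab$range[i])^2 / (2 * sd_r^2))
    ku <- exp(-(ug - u0)^2 / (2 * sd_u^2))
    field <- field + tab$amplitude[i] * (kr %o% ku)
  }
  if (radar$noise_sigma > 0) {
    nc <- length(field)
    z <- complex(real = stats::rnorm(nc, 0, radar$noise_sigma / sqrt(2)),
                 imaginary = stats::rnorm(nc, 0, radar$noise_sigma / sqrt(2)))
    field <- matrix(Mod(field + z), nrow(field), ncol(field))
  }
  range_azimuth_frame(field, radar, timestamp)
}
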