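#' Discrete Ricker (Mexican hat) kernel
#'
#' `psi(t) = (1 - (t/a)^2) exp(-t^2 / (2 a^2))` sampled on integer lags
#' `-L..L` with `L = ceiling(support * a)`, then mean-subtracted (exact zero
#' sum) and L2-normalized. The kernel peaks at the centre and crosses zero at
#' `t = +/- a`.
#'
#' @param scale Scale `a` in samples (> 0; may be fractional).
#' @param support Half-support in units of `a` (default 4, i.e. total support
#'   `8 a`).
#' @return Numeric kernel of odd length `2 L + 1`.
#' @export
ricker_kernel <- function(scale, support = 4) {
  if (scale <= 0) stop("scale must be positive")
  if (support < 4) stop("support must be at least 4 scales (total 8a)")
  L <- ceiling(support * scale)
  t <- (-L):L
  psi <- (1 - (t / scale)^2) * exp(-t^2 / (2 * scale^2))
  psi <- psi - mean(psi)
  psi / sqrt(sum(psi^2))
}

#' Continuous wavelet transform of a position signal (Ricker filter bank)
#'
#' Convolves the signal with a Ricker kernel at each scale (FFT-based,
#' same-length output, reflective boundary padding). Being zero-mean with
#' vanishing first moment, the Ricker annihilates constant and linear trends:
#' coefficients respond to changes in the way of moving, not to steady
#' motion.
#'
#' @param signal Positions along one axis (numeric vector).
#' @param scales Scales in samples (each > 0).
#' @param axis Optional axis tag ("x" or "y") stored with the result.
#' @return An object of class `cwt_result`: `scales`, `coefficients` (matrix,
#'   scales x time), `axis`.
#' @export
ricker_cwt <- function(signal, scales, axis = NULL) {
  if (length(scales) == 0) stop("scale list is empty")
  n <- length(signal)
  Lmax <- ceiling(4 * max(scales))
  if (n <= 2 * Lmax + 1)
    stop("signal shorter than the largest kernel support")
  # reflective padding by the largest half-support; one shared signal FFT
  pad <- c(signal[(Lmax + 1):2], signal, signal[(n - 1):(n - Lmax)])
  np <- length(pad)
  M <- stats::nextn(np + 2 * Lmax + 1, 2)
  Fx <- stats::fft(c(pad, rep(0, M - np)))
  co <- matrix(NA_real_, length(scales), n)
  for (i in seq_along(scales)) {
    k <- ricker_kernel(scales[i])
    L <- (length(k) - 1) / 2
    Fk <- stats::fft(c(k, rep(0, M - length(k))))
    full <- Re(stats::fft(Fx * Fk, inverse = TRUE)) / M
    co[i, ] <- full[(Lmax + L + 1):(Lmax + L + n)]
  }
  structure(list(scales = scales, coefficients = co, axis = axis),
            class = "cwt_result")
}

## samples of margin excluded at each end of a mask run, per scale
.cwt_margin <- function(scale) ceiling(4 * scale)

## forward / backward run lengths of TRUE values
.run_depth <- function(mask) {
  n <- length(mask)
  f <- integer(n); b <- integer(n)
  acc <- 0L
  for (i in seq_len(n)) { acc <- if (mask[i]) acc + 1L else 0L; f[i] <- acc }
  acc <- 0L
  for (i in rev(seq_len(n))) { acc <- if (mask[i]) acc + 1L else 0L; b[i] <- acc }
  list(fwd = f, bwd = b)
}

#' Count movement transitions in a wavelet coefficient field
#'
#' A transition is a strict local maximum of the absolute coefficient field
#' over its 8 neighbours in the (scale x time) plane whose value reaches
#' `rel_threshold` times the field maximum. Maxima are counted inside the
#' phase mask, excluding a per-scale boundary margin of one kernel
#' half-support (4 scales) at the mask and signal edges. Plateau cells count
#' once, at their first position in scale-major order.
#'
#' @param cwt A `cwt_result`.
#' @param phase_mask Logical vector (length = signal) selecting the phase.
#' @param rel_threshold Relative threshold in (0, 1) (default 0.1).
#' @param field_max Reference maximum for the threshold; defaults to the
#'   maximum absolute coefficient of this field. Pass a shared value to
#'   compare counts across phases or axes on one scale.
#' @return An object of class `transition_count`: `count` and a data.frame
#'   `maxima` with columns `scale_index`, `scale`, `time_index`.
#' @export
count_transitions <- function(cwt, phase_mask, rel_threshold = 0.1,
                              field_max = NULL) {
  stopifnot(inherits(cwt, "cwt_result"),
            rel_threshold > 0, rel_threshold < 1)
  A <- abs(cwt$coefficients)
  ns <- nrow(A); n <- ncol(A)
  if (length(phase_mask) != n) stop("phase mask length must match the signal")
  if (!any(phase_mask)) stop("empty phase mask")
  if (is.null(field_max)) field_max <- max(A)
  empty <- structure(list(count = 0L,
                          maxima = data.frame(scale_index = integer(),
                                              scale = numeric(),
                                              time_index = integer())),
                     class = "transition_count")
  if (field_max < 1e-12) return(empty)
  thr <- rel_threshold * field_max

  depth <- .run_depth(phase_mask)
  P <- matrix(-Inf, ns + 2, n + 2)
  P[2:(ns + 1), 2:(n + 1)] <- A
  ctr <- P[2:(ns + 1), 2:(n + 1)]
  sh <- function(dr, dc) P[(2 + dr):(ns + 1 + dr), (2 + dc):(n + 1 + dc)]
  # strict against earlier cells in scale-major (row, col) order, >= later
  cand <- ctr > sh(-1, -1) & ctr > sh(-1, 0) & ctr > sh(-1, 1) &
    ctr > sh(0, -1) & ctr >= sh(0, 1) &
    ctr >= sh(1, -1) & ctr >= sh(1, 0) & ctr >= sh(1, 1) &
    ctr >= thr
  for (i in seq_len(ns)) {
    m <- .cwt_margin(cwt$scales[i])
    ok <- phase_mask & depth$fwd > m & depth$bwd > m
    cand[i, !ok] <- FALSE
  }
  idx <- which(cand, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  structure(list(count = nrow(idx),
                 maxima = data.frame(scale_index = idx[, 1],
                                     scale = cwt$scales[idx[, 1]],
                                     time_index = idx[, 2])),
            class = "transition_count")
}

#' Default wavelet scale set (seconds)
#'
#' Eight log-spaced scales from 0.2 s to 2 s. The upper scale is bounded by
#' the need to resolve changes a few seconds apart inside a 60-s phase (a
#' Ricker of scale a has support 8a, and its boundary margin erodes 4a from
#' each mask edge).
#'
#' @return Numeric vector of 8 scales in seconds.
#' @export
default_wavelet_scales <- function() exp(seq(log(0.2), log(2), length.out = 8))

#' Wavelet transition counts per axis and phase
#'
#' Applies the Ricker filter bank to the raw x (lateral) and y (longitudinal)
#' position signals of the whole trajectory and counts coefficient-field
#' local maxima within each analysed phase. The detection threshold is
#' relative to the per-axis field maximum over the analysed phases, so a
#' phase with suppressed movement yields fewer counts.
#'
#' @param traj A `sheep_trajectory` covering the analysed phases.
#' @param scales_s Scales in seconds (default [default_wavelet_scales()]).
#' @param phases Phases to analyse (default "2" and "3").
#' @param rel_threshold Relative threshold (default 0.1).
#' @return A data.frame with columns `axis` ("x"/"y"), `phase`, `count`.
#' @export
transition_features <- function(traj, scales_s = default_wavelet_scales(),
                                phases = c("2", "3"), rel_threshold = 0.1) {
  if (!all(phases %in% traj$phase))
    stop("trajectory does not cover phases: ",
         paste(setdiff(phases, traj$phase), collapse = ", "))
  rate <- traj_rate(traj)
  scales <- scales_s * rate
  out <- list()
  for (axis in c("x", "y")) {
    cw <- ricker_cwt(traj[[axis]], scales, axis = axis)
    in_any <- traj$phase %in% phases
    fmax <- max(abs(cw$coefficients[, in_any, drop = FALSE]))
    for (ph in phases) {
      tc <- count_transitions(cw, traj$phase == ph, rel_threshold,
                              field_max = fmax)
      out[[length(out) + 1L]] <- data.frame(axis = axis, phase = ph,
                                            count = tc$count)
    }
  }
  do.call(rbind, out)
}
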