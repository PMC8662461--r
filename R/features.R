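#' Segment a trajectory into 1-s windows
#'
#' Windows are non-overlapping and contiguous, cut independently within each
#' experimental phase. A trailing partial window shorter than half the window
#' length is dropped; longer partials are kept.
#'
#' @param traj A `sheep_trajectory` sampled at a constant rate.
#' @param window_s Window length in seconds (default 1).
#' @return A list of trajectory slices (data.frames), each carrying its
#'   `window_start` and `phase`.
#' @export
## window index ranges (start, end) per phase run
.window_ranges <- function(traj, window_s) {
  rate <- traj_rate(traj)
  dt <- 1 / rate
  if (nrow(traj) > 1 && max(abs(diff(traj$time) - dt)) > dt / 10)
    stop("trajectory is not sampled at a constant rate")
  n_per <- max(2L, as.integer(round(window_s * rate)))
  runs <- rle(traj$phase)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  i0 <- integer(0); i1 <- integer(0)
  for (r in seq_along(runs$values)) {
    len <- runs$lengths[r]
    n_full <- len %/% n_per
    n_win <- n_full + ((len - n_full * n_per) >= ceiling(n_per / 2))
    if (n_win == 0) next
    w0 <- starts[r] + (seq_len(n_win) - 1L) * n_per
    i0 <- c(i0, w0)
    i1 <- c(i1, pmin(w0 + n_per - 1L, ends[r]))
  }
  if (length(i0) == 0) stop("trajectory shorter than one window")
  list(i0 = i0, i1 = i1)
}

segment_windows <- function(traj, window_s = 1.0) {
  rg <- .window_ranges(traj, window_s)
  lapply(seq_along(rg$i0), function(w)
    traj[rg$i0[w]:rg$i1[w], , drop = FALSE])
}

#' Movement descriptors of one window
#'
#' From a window of positions: total path length (sum of step lengths), mean
#' speed (path length over the window duration), sinuosity (path length over
#' net displacement, floored), and the mean magnitudes of the lateral (x,
#' across-width) and longitudinal (y, along-length) per-step speed
#' components.
#'
#' Sinuosity is `max(path, floor) / max(net, floor)` with `floor` one
#' range-bin width by default: it is 1 for a straight path and for a
#' stationary window (degenerate 0/0 case), >= 1 always, and stays finite for
#' closed loops where the raw ratio diverges.
#'
#' @param window A trajectory slice with at least 2 samples.
#' @param sinuosity_floor Net-displacement floor in metres (default 0.05, one
#'   range bin at 3 GHz bandwidth).
#' @return A one-row data.frame: `window_start`, `phase`, `mean_speed`,
#'   `sinuosity`, `path_length`, `lateral_speed`, `longitudinal_speed`.
#' @export
window_features <- function(window, sinuosity_floor = 0.05) {
  n <- nrow(window)
  if (n < 2) stop("window needs at least 2 samples")
  dtv <- diff(window$time)
  if (any(dtv <= 0)) stop("window timestamps must be strictly increasing")
  dx <- diff(window$x); dy <- diff(window$y)
  steps <- sqrt(dx^2 + dy^2)
  path <- sum(steps)
  duration <- window$time[n] - window$time[1]
  net <- sqrt((window$x[n] - window$x[1])^2 + (window$y[n] - window$y[1])^2)
  data.frame(window_start = window$time[1],
             phase = window$phase[1],
             mean_speed = path / duration,
             sinuosity = max(path, sinuosity_floor) / max(net, sinuosity_floor),
             path_length = path,
             lateral_speed = mean(abs(dx) / dtv),
             longitudinal_speed = mean(abs(dy) / dtv),
             stringsAsFactors = FALSE)
}

#' Per-window movement features of a whole trajectory
#'
#' Convenience wrapper: [segment_windows()] then [window_features()] per
#' window.
#'
#' @inheritParams segment_windows
#' @inheritParams window_features
#' @return A data.frame of class `window_features`, one row per window.
#' @export
movement_features <- function(traj, window_s = 1.0, sinuosity_floor = 0.05) {
  rg <- .window_ranges(traj, window_s)
  n <- nrow(traj)
  dtv <- diff(traj$time)
  dx <- diff(traj$x); dy <- diff(traj$y)
  cs_step <- c(0, cumsum(sqrt(dx^2 + dy^2)))
  cs_lat <- c(0, cumsum(abs(dx) / dtv))
  cs_lon <- c(0, cumsum(abs(dy) / dtv))
  i0 <- rg$i0; i1 <- rg$i1
  nstep <- i1 - i0
  path <- cs_step[i1] - cs_step[i0]
  duration <- traj$time[i1] - traj$time[i0]
  net <- sqrt((traj$x[i1] - traj$x[i0])^2 + (traj$y[i1] - traj$y[i0])^2)
  out <- data.frame(
    window_start = traj$time[i0],
    phase = traj$phase[i0],
    mean_speed = path / duration,
    sinuosity = pmax(path, sinuosity_floor) / pmax(net, sinuosity_floor),
    path_length = path,
    lateral_speed = (cs_lat[i1] - cs_lat[i0]) / nstep,
    longitudinal_speed = (cs_lon[i1] - cs_lon[i0]) / nstep,
    stringsAsFactors = FALSE)
  class(out) <- c("window_features", "data.frame")
  out
}

.FEATURE_COLS <- c("mean_speed", "sinuosity", "path_length",
                   "lateral_speed", "longitudinal_speed")

## best-of-restarts VVV mixture fit at one component count.
## The prior scale is ridge-regularized: window features can be exactly
## collinear (path length = mean speed x window duration for full windows),
## which makes the default data-covariance prior scale singular.
.fit_vvv <- function(X, G, n_restarts) {
  S <- stats::cov(X)
  S <- S + diag(1e-4 * mean(diag(S)), ncol(X))
  prior <- mclust::priorControl(scale = S)
  best <- tryCatch(
    suppressWarnings(mclust::Mclust(X, G = G, modelNames = "VVV",
                                    prior = prior, verbose = FALSE)),
    error = function(e) NULL)
  for (r in seq_len(max(0L, n_restarts - 1L))) {
    f <- tryCatch(
      suppressWarnings(mclust::Mclust(
        X, G = G, modelNames = "VVV", prior = prior, verbose = FALSE,
        initialization = list(hcPairs = mclust::hcRandomPairs(X)))),
      error = function(e) NULL)
    if (!is.null(f) && is.finite(f$loglik) &&
        (is.null(best) || !is.finite(best$loglik) || f$loglik > best$loglik))
      best <- f
  }
  if (!is.null(best) && is.finite(best$loglik)) best else NULL
}

#' Discover behavioural classes by Gaussian-mixture fitting with AIC
#'
#' Fits full-covariance Gaussian mixtures to the standardized window features
#' for each candidate class count k, scores each fit with
#' `AIC = 2 p - 2 logL` (p = free parameter count), and keeps the k with the
#' lowest AIC. Each k is fitted `n_restarts` times (the deterministic
#' model-based hierarchical initialization plus random-agglomeration
#' restarts), keeping the best log-likelihood; a conjugate prior
#' (`mclust::priorControl()`) regularizes the covariances against the
#' degenerate likelihood spikes of full-covariance EM.
#'
#' Components are then given semantic names from their class means:
#' fast if the mean speed exceeds `max(pooled median speed, fast_speed_min)`,
#' tortuous if the mean sinuosity exceeds
#' `max(pooled median sinuosity, tortuous_sinuosity_min)`. The absolute
#' floors make the labels robust when the cohort has no genuinely fast (or
#' tortuous) windows, in which case a pooled median alone would split hairs
#' inside a single cloud.
#'
#' @param features A `window_features` data.frame (or anything with the five
#'   feature columns).
#' @param k_range Candidate class counts (default 1 to 15).
#' @param n_restarts EM initializations per k (default 10).
#' @param seed Optional seed (restart and subset randomness).
#' @param max_fit_n Windows above which the mixture is fitted on a random
#'   subset of this size and the remaining windows are classified by the
#'   fitted model (default 3000).
#' @param fast_speed_min,tortuous_sinuosity_min Absolute floors for the
#'   semantic labelling thresholds (m/s and dimensionless; defaults 0.25 and
#'   2).
#' @return An object of class `class_model`: `n_classes`, `weights`, `means`
#'   (features x classes, original units), `aic_curve` (named by k),
#'   `loglik`, `labels` (component index per window), `class_names` (semantic
#'   label per component).
#' @importFrom mclust Mclust mclustBIC priorControl hcRandomPairs
#' @export
fit_movement_classes <- function(features, k_range = 1:15, n_restarts = 10,
                                 seed = NULL, max_fit_n = 3000,
                                 fast_speed_min = 0.25,
                                 tortuous_sinuosity_min = 2) {
  X <- as.matrix(as.data.frame(features)[, .FEATURE_COLS])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate (constant) feature column: ",
                          paste(.FEATURE_COLS[sds == 0], collapse = ", "))
  mus <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mus), 2, sds, "/")
  n <- nrow(Xs)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1 & 2 * k_range <= n]
  if (length(k_range) == 0) stop("too few windows for any candidate k")

  if (!is.null(seed)) set.seed(seed)
  fit_idx <- if (n > max_fit_n) sample.int(n, max_fit_n) else seq_len(n)
  Xf <- Xs[fit_idx, , drop = FALSE]

  fits <- vector("list", length(k_range))
  aic <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    fit <- .fit_vvv(Xf, k_range[i], n_restarts)
    if (!is.null(fit)) {
      fits[[i]] <- fit
      aic[i] <- 2 * fit$df - 2 * fit$loglik
    }
  }
  names(aic) <- k_range
  if (all(is.na(aic))) stop("no mixture model could be fitted")
  best <- which.min(aic)
  fit <- fits[[best]]
  k <- k_range[best]
  labels <- if (n > max_fit_n)
    as.integer(stats::predict(fit, newdata = Xs)$classification)
  else as.integer(fit$classification)

  mean_orig <- fit$parameters$mean * sds + mus   # recycle by column
  if (is.null(dim(mean_orig))) mean_orig <- matrix(mean_orig, ncol = 1)
  rownames(mean_orig) <- .FEATURE_COLS
  thr_speed <- max(stats::median(X[, "mean_speed"]), fast_speed_min)
  thr_sin <- max(stats::median(X[, "sinuosity"]), tortuous_sinuosity_min)
  fastc <- mean_orig["mean_speed", ] > thr_speed
  tortc <- mean_orig["sinuosity", ] > thr_sin
  class_names <- ifelse(fastc,
                        ifelse(tortc, "fast_tortuous", "fast"),
                        ifelse(tortc, "slow_tortuous", "slow"))
  structure(list(n_classes = k,
                 weights = fit$parameters$pro,
                 means = mean_orig,
                 covariances = fit$parameters$variance$sigma,
                 aic_curve = aic,
                 loglik = fit$loglik,
                 labels = labels,
                 class_names = unname(class_names),
                 feature_names = .FEATURE_COLS,
                 scaling = list(center = mus, scale = sds),
                 thresholds = c(speed = thr_speed, sinuosity = thr_sin)),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("Movement class model: k = %d (AIC-selected of %s)\n",
              x$n_classes, paste(range(as.integer(names(x$aic_curve))),
                                 collapse = "-")))
  cat("  classes:", paste(sprintf("%s (w=%.2f)", x$class_names, x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Per-phase occupancy of the movement classes
#'
#' Proportion of windows assigned to each mixture component, within each
#' phase; rows sum to 1.
#'
#' @param model A `class_model`.
#' @param phases Phase label per window (aligned with `model$labels`).
#' @return A matrix, phases x classes, of proportions; column names carry the
#'   semantic class labels.
#' @export
class_time_rates <- function(model, phases) {
  if (length(phases) != length(model$labels))
    stop("phases must align with the model's window labels")
  tab <- table(phase = phases,
               class = factor(model$labels, levels = seq_len(model$n_classes)))
  if (any(rowSums(tab) == 0)) stop("empty phase")
  m <- sweep(unclass(tab), 1, rowSums(tab), "/")
  colnames(m) <- paste0(model$class_names, seq_len(model$n_classes))
  m
}

#' Proportion of fast movement among the non-tortuous classes
#'
#' `fast / (slow + fast)` over the windows of one phase, ignoring the
#' tortuous classes, using the semantic class labels.
#'
#' @param model A `class_model`.
#' @param phases Phase label per window.
#' @param phase Which phase to evaluate.
#' @return A fraction in `[0, 1]`.
#' @export
fast_movement_proportion <- function(model, phases, phase) {
  if (length(phases) != length(model$labels))
    stop("phases must align with the model's window labels")
  labs <- model$class_names[model$labels[phases == phase]]
  n_fast <- sum(labs == "fast")
  n_slow <- sum(labs == "slow")
  if (n_fast + n_slow == 0)
    stop("no slow or fast windows in phase ", phase)
  n_fast / (n_fast + n_slow)
}
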