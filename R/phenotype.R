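.PHENO_FEATURES <- c("fast_prop_p2", "fast_prop_p3",
                     "wavelet_x_p2", "wavelet_x_p3",
                     "wavelet_y_p2", "wavelet_y_p3",
                     "heatmap_p2", "heatmap_p3")

## fast/(slow+fast) from semantic window labels
.fast_prop <- function(class_names, phases, phase) {
  labs <- class_names[phases == phase]
  n_fast <- sum(labs == "fast"); n_slow <- sum(labs == "slow")
  if (n_fast + n_slow == 0) return(NA_real_)
  n_fast / (n_fast + n_slow)
}

#' Per-sheep behavioural feature table for a simulated cohort
#'
#' Runs the full estimator pipeline on each session's trajectory (ground
#' truth by default, or the radar-recovered track): 1-s window features,
#' movement-class labels from one pooled AIC-selected Gaussian mixture across
#' the cohort (or per-animal fits), wavelet transition counts per axis, and
#' heatmap scores — each for phases 2 and 3 — plus the animal's covariates.
#'
#' @param sessions List of `radar_session`s from [simulate_cohort()].
#' @param use "ground_truth" or "radar" (requires sessions with frames).
#' @param k_range Candidate class counts for the mixture (default 1:6 for
#'   cohort runs; use 1:15 for single-animal analyses).
#' @param n_restarts EM initializations per candidate k (default 5 for
#'   cohort runs).
#' @param max_fit_n Window-count cap for mixture fitting (see
#'   [fit_movement_classes()]).
#' @param pooled Fit one mixture on all animals' windows (default) rather
#'   than one per animal.
#' @param window_s Window length (s).
#' @param heatmap_threshold Dwell threshold (s) for the heatmap score.
#' @param scales_s Wavelet scales in seconds.
#' @param rel_threshold Relative threshold for transition counting.
#' @param seed Optional seed (mixture subset initialization).
#' @param threshold Detection threshold when `use = "radar"`.
#' @return A data.frame of class `phenotype_table`: `sheep_id`, `docility`,
#'   `sociability`, and the eight feature columns (`fast_prop`, `wavelet_x`,
#'   `wavelet_y`, `heatmap` for phases 2 and 3).
#' @export
cohort_phenotypes <- function(sessions, use = c("ground_truth", "radar"),
                              k_range = 1:6, n_restarts = 5,
                              max_fit_n = 1500,
                              pooled = TRUE, window_s = 1.0,
                              heatmap_threshold = 0.2,
                              scales_s = default_wavelet_scales(),
                              rel_threshold = 0.1, seed = NULL,
                              threshold = 5) {
  use <- match.arg(use)
  arena <- sessions[[1]]$arena
  grid <- build_grid(arena)
  phases <- c("2", "3")

  trajs <- lapply(sessions, function(s)
    if (use == "ground_truth") s$ground_truth else track_session(s, threshold))
  featl <- lapply(trajs, function(tr) {
    f <- movement_features(tr, window_s)
    f[f$phase %in% phases, , drop = FALSE]
  })

  if (pooled) {
    all_feat <- do.call(rbind, featl)
    model <- fit_movement_classes(all_feat, k_range = k_range,
                                  n_restarts = n_restarts,
                                  max_fit_n = max_fit_n, seed = seed)
    labs <- model$class_names[model$labels]
    idx <- rep(seq_along(featl), vapply(featl, nrow, 1L))
  }

  rows <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    f_i <- featl[[i]]
    if (pooled) {
      labs_i <- labs[idx == i]
    } else {
      m_i <- fit_movement_classes(f_i, k_range = k_range,
                                  n_restarts = n_restarts, seed = seed)
      labs_i <- m_i$class_names[m_i$labels]
    }
    wl <- transition_features(trajs[[i]], scales_s = scales_s,
                              phases = phases, rel_threshold = rel_threshold)
    dw <- dwell_times(trajs[[i]], grid)
    rows[[i]] <- data.frame(
      sheep_id = sessions[[i]]$sheep_id,
      docility = sessions[[i]]$covariates$docility,
      sociability = sessions[[i]]$covariates$sociability,
      fast_prop_p2 = .fast_prop(labs_i, f_i$phase, "2"),
      fast_prop_p3 = .fast_prop(labs_i, f_i$phase, "3"),
      wavelet_x_p2 = wl$count[wl$axis == "x" & wl$phase == "2"],
      wavelet_x_p3 = wl$count[wl$axis == "x" & wl$phase == "3"],
      wavelet_y_p2 = wl$count[wl$axis == "y" & wl$phase == "2"],
      wavelet_y_p3 = wl$count[wl$axis == "y" & wl$phase == "3"],
      heatmap_p2 = heatmap_score(dw, heatmap_threshold, phase = "2"),
      heatmap_p3 = heatmap_score(dw, heatmap_threshold, phase = "3"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Assemble and standardize the per-sheep feature matrix
#'
#' Validates completeness (every animal has all eight features), z-scores
#' each feature across the cohort, and drops zero-variance features with a
#' warning.
#'
#' @param phenotypes A `phenotype_table` (or data.frame with the eight
#'   feature columns and covariates).
#' @return An object of class `phenotype_records`: the input `records`, the
#'   standardized `features` matrix, and `feature_names`.
#' @export
assemble_features <- function(phenotypes) {
  d <- as.data.frame(phenotypes)
  missing_cols <- setdiff(.PHENO_FEATURES, names(d))
  if (length(missing_cols) > 0)
    stop("missing estimator columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(d) < 3)
    stop("cohort standardization needs at least 3 animals")
  X <- as.matrix(d[, .PHENO_FEATURES])
  if (any(!is.finite(X)))
    stop("missing estimator values for some animals")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  structure(list(records = d, features = scale(X),
                 feature_names = colnames(X)),
            class = "phenotype_records")
}

#' Correlation-matrix principal component analysis
#'
#' Eigen-decomposition of the feature correlation matrix (the features have
#' incommensurate units, so the standardized PCA is used). Components are
#' ordered by eigenvalue; each loading vector's sign is fixed so that its
#' largest-magnitude loading is positive. The number of retained components
#' follows the Kaiser-Guttman criterion.
#'
#' @param x A `phenotype_records` object or a numeric matrix (animals x
#'   features).
#' @return An object of class `pca_summary`: `eigenvalues` (descending),
#'   `variance_explained` (fractions summing to 1), `loadings` (features x
#'   components), `scores` (animals x components), `n_retained`.
#' @export
phenotype_pca <- function(x) {
  X <- if (inherits(x, "phenotype_records")) x$features else
    scale(as.matrix(x))
  if (nrow(X) < 3 || ncol(X) < 2) stop("need >= 3 animals and >= 2 features")
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- X %*% V
  structure(list(eigenvalues = ev,
                 variance_explained = ev / sum(ev),
                 loadings = V, scores = scores,
                 n_retained = kaiser_guttman(ev)),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d features, %d retained (Kaiser-Guttman)\n",
              length(x$eigenvalues), x$n_retained))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Kaiser-Guttman component retention
#'
#' Number of eigenvalues strictly greater than 1 (for a correlation-matrix
#' PCA, components carrying more variance than a single standardized
#' feature). An eigenvalue of exactly 1 is not retained.
#'
#' @param eigenvalues Eigenvalues sorted in non-increasing order.
#' @return Integer count of retained components.
#' @export
#' @examples
#' kaiser_guttman(c(2.893, 1.738, 0.974, 0.833, 0.564, 0.492)) # 2
kaiser_guttman <- function(eigenvalues) {
  if (length(eigenvalues) == 0) stop("empty eigenvalue list")
  if (is.unsorted(rev(eigenvalues), strictly = FALSE) &&
      any(diff(eigenvalues) > 1e-8))
    stop("eigenvalues must be sorted in non-increasing order")
  sum(eigenvalues > 1)
}

#' Pearson agreement between two estimator series
#'
#' Product-moment correlation with the two-sided t-distribution p-value; used
#' to compare tracker-derived estimators (radar vs infrared cells vs video).
#'
#' @param series_a,series_b Numeric vectors of equal length >= 3.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_agreement <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) stop("series lengths differ")
  if (length(series_a) < 3) stop("need at least 3 paired values")
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("zero variance in a series")
  ct <- stats::cor.test(series_a, series_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(series_a))
}

#' Simple regressions of PC scores on covariates
#'
#' Ordinary least-squares regression of each retained component score on each
#' covariate, one pair at a time; the tidy table downstream mixed-model
#' analyses start from.
#'
#' @param pc_scores Numeric matrix of component scores (animals x components,
#'   named columns).
#' @param covariates Data.frame of per-animal covariates (numeric columns).
#' @return A data.frame with `component`, `covariate`, `slope`, `se`, `p`.
#' @export
covariate_association <- function(pc_scores, covariates) {
  pc_scores <- as.matrix(pc_scores)
  covariates <- as.data.frame(covariates)
  if (nrow(pc_scores) < 10) stop("need at least 10 animals")
  if (nrow(pc_scores) != nrow(covariates)) stop("row counts differ")
  out <- list()
  for (pc in colnames(pc_scores)) {
    for (cv in names(covariates)) {
      x <- covariates[[cv]]
      if (!is.numeric(x)) next
      if (stats::sd(x) == 0) stop("constant covariate: ", cv)
      fit <- stats::lm(pc_scores[, pc] ~ x)
      cf <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        component = pc, covariate = cv,
        slope = cf[2, 1], se = cf[2, 2], p = cf[2, 4],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
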