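#' Covariate specification for session simulation
#'
#' Per-animal docility and sociability scores are drawn from normal
#' distributions and coupled log-linearly to the propensities of the moving
#' (fast) latent states: the chain's stationary distribution is re-targeted
#' as `softmax(log pi0 + I_moving * eta)` where, in phase 2,
#' `eta = beta_sociability * sociability + beta_docility * docility`, and in
#' phase 3 `eta` additionally includes `log(phase3_activity)`. Signs follow
#' the cohort-level findings: sociability increases movement, docility
#' decreases it, and phase 3 (conspecifics visible, human present) suppresses
#' movement overall.
#'
#' @param docility_mean,docility_sd,sociability_mean,sociability_sd
#'   Covariate distributions (standardized scores by default).
#' @param beta_sociability Log-propensity effect of sociability on the moving
#'   states in phase 2 (default 0.4, positive).
#' @param beta_docility Same for docility (default -0.15, negative).
#' @param phase3_activity Multiplier (< 1 suppresses movement) on the
#'   moving-state propensities in phase 3 (default 0.35).
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(docility_mean = 0, docility_sd = 1,
                           sociability_mean = 0, sociability_sd = 1,
                           beta_sociability = 0.4, beta_docility = -0.15,
                           phase3_activity = 0.35) {
  stopifnot(docility_sd >= 0, sociability_sd >= 0, phase3_activity > 0)
  structure(list(docility_mean = docility_mean, docility_sd = docility_sd,
                 sociability_mean = sociability_mean,
                 sociability_sd = sociability_sd,
                 beta_sociability = beta_sociability,
                 beta_docility = beta_docility,
                 phase3_activity = phase3_activity),
            class = "covariate_spec")
}

## indices of the "moving" states (speed above the median state speed)
.moving_states <- function(model) {
  sp <- model$states$speed_mean
  which(sp > stats::median(sp))
}

## re-target the chain's stationary distribution log-linearly on the moving
## states, preserving the average stickiness of the base matrix
.adjust_model <- function(model, eta_moving) {
  P <- model$transition_matrix
  s <- mean(diag(P))
  pi0 <- stationary_distribution(P)
  lw <- log(pi0)
  lw[.moving_states(model)] <- lw[.moving_states(model)] + eta_moving
  pi1 <- exp(lw - max(lw)); pi1 <- pi1 / sum(pi1)
  P1 <- s * diag(length(pi1)) +
    (1 - s) * matrix(pi1, length(pi1), length(pi1), byrow = TRUE)
  trajectory_model(model$states, P1)
}

#' Generate one complete simulated arena-test session
#'
#' Draws the animal's covariates, simulates the three-phase ground-truth
#' trajectory at the radar frame rate (with covariate- and phase-dependent
#' movement propensities, see [covariate_spec()]), derives the infrared
#' beam-crossing events, and optionally synthesizes the radar frames:
#' background (animal absent) frames for clutter estimation plus one frame
#' per trajectory sample. All randomness flows from `seed`.
#'
#' @param arena,radar,model,cov_spec Configuration objects.
#' @param seed Integer seed (one seed determines the whole session).
#' @param frames "map" for map-level frames, "signal" for raw beat-signal
#'   frames, or "none" to skip frame synthesis (trajectory-only studies).
#' @param n_background Number of background frames (>= 1; default 120).
#' @param scene Clutter scene; default wall scatterers of the arena.
#' @param target_amplitude Echo amplitude of the sheep.
#' @param sheep_id Identifier stored with the session.
#' @return An object of class `radar_session`: list with `sheep_id`,
#'   `covariates` (docility, sociability), `ground_truth` trajectory,
#'   `infrared_events`, `background_frames`, `frames`, and the configuration
#'   objects.
#' @export
generate_session <- function(arena = arena_config(), radar = radar_config(),
                             model = sheep_movement_model(),
                             cov_spec = covariate_spec(), seed = NULL,
                             frames = c("none", "map", "signal"),
                             n_background = 120,
                             scene = arena_clutter_scene(arena),
                             target_amplitude = 10,
                             sheep_id = "sheep01") {
  frames <- match.arg(frames)
  if (frames != "none" && n_background < 1)
    stop("at least one background frame must be requested")
  if (!is.null(seed)) set.seed(seed)
  doc <- stats::rnorm(1, cov_spec$docility_mean, cov_spec$docility_sd)
  soc <- stats::rnorm(1, cov_spec$sociability_mean, cov_spec$sociability_sd)
  eta_cov <- cov_spec$beta_sociability * soc + cov_spec$beta_docility * doc
  eta_phase <- c(eta_cov, eta_cov, eta_cov + log(cov_spec$phase3_activity))

  rate <- radar$frame_rate
  dt <- 1 / rate
  segs <- vector("list", 3)
  t0 <- 0; start <- NULL; start_state <- NULL
  for (ph in 1:3) {
    m_ph <- .adjust_model(model, eta_phase[ph])
    segs[[ph]] <- simulate_trajectory(m_ph, arena, arena$phase_durations[ph],
                                      rate = rate, start = start,
                                      start_state = start_state,
                                      t0 = t0, phase = as.character(ph))
    last <- nrow(segs[[ph]])
    start <- c(segs[[ph]]$x[last], segs[[ph]]$y[last])
    start_state <- match(segs[[ph]]$state[last], model$states$name)
    t0 <- segs[[ph]]$time[last] + dt
  }
  gt <- do.call(rbind, lapply(segs, as.data.frame))
  gt <- trajectory(gt$time, gt$x, gt$y, phase = gt$phase,
                   source = "ground_truth", rate = rate,
                   extra = list(state = gt$state))

  events <- infrared_events(gt, arena)

  bg <- list(); fr <- list()
  if (frames != "none") {
    synth <- if (frames == "map") synthesize_map else function(...) {
      frame_to_map(synthesize_beat_signal(...))
    }
    bg <- lapply(seq_len(n_background), function(i)
      synth(NULL, scene, radar, timestamp = (i - 1) * dt))
    fr <- lapply(seq_len(nrow(gt)), function(i)
      synth(c(gt$x[i], gt$y[i]), scene, radar,
            target_amplitude = target_amplitude, timestamp = gt$time[i]))
  }
  structure(list(sheep_id = sheep_id,
                 covariates = list(docility = doc, sociability = soc),
                 ground_truth = gt, infrared_events = events,
                 background_frames = bg, frames = fr,
                 arena = arena, radar = radar, model = model,
                 cov_spec = cov_spec, scene = scene),
            class = "radar_session")
}

#' @export
print.radar_session <- function(x, ...) {
  cat(sprintf("Arena-test session %s: %d samples, %d background / %d scene frames\n",
              x$sheep_id, nrow(x$ground_truth),
              length(x$background_frames), length(x$frames)))
  cat(sprintf("  docility %.2f, sociability %.2f, %d infrared events\n",
              x$covariates$docility, x$covariates$sociability,
              nrow(x$infrared_events)))
  invisible(x)
}

#' Simulate a cohort of arena-test sessions
#'
#' One session per animal, each driven by a sub-seed derived from `seed`.
#'
#' @inheritParams generate_session
#' @param n_sheep Number of animals (default 58, the study cohort size).
#' @return A list of `radar_session` objects.
#' @export
simulate_cohort <- function(n_sheep = 58, arena = arena_config(),
                            radar = radar_config(),
                            model = sheep_movement_model(),
                            cov_spec = covariate_spec(), seed = NULL,
                            frames = "none", n_background = 120) {
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max, n_sheep)
  lapply(seq_len(n_sheep), function(i)
    generate_session(arena, radar, model, cov_spec, seed = sub[i],
                     frames = frames, n_background = n_background,
                     sheep_id = sprintf("sheep%02d", i)))
}

#' Recover the animal's trajectory from a session's radar frames
#'
#' The full tracking chain: estimate clutter statistics from the background
#' frames, clutter-normalize each scene frame, detect the per-frame peak, and
#' assemble the 2D track with constant-velocity gap filling.
#'
#' @param session A `radar_session` generated with frames.
#' @param threshold Detection threshold on the normalized amplitude D.
#' @param eps Guard for zero-variance cells in the normalization.
#' @return A `sheep_trajectory` (source "radar").
#' @export
track_session <- function(session, threshold = 5, eps = 1e-12) {
  if (length(session$frames) == 0)
    stop("session has no radar frames (generated with frames = 'none')")
  cl <- estimate_clutter(session$background_frames)
  dets <- lapply(session$frames, function(f)
    detect_target(normalize_frame(f, cl, eps), threshold))
  df <- do.call(rbind, lapply(dets, function(d)
    data.frame(time = d$timestamp, range = d$range,
               azimuth_deg = d$azimuth_deg, valid = d$valid)))
  assemble_track(df, rate = session$radar$frame_rate, arena = session$arena)
}
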