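# shared fixtures built in code

# isotropic two-mode feature cloud: unit within-component sd, centres
# `sep` apart in euclidean (standardized) distance
iso_two_modes <- function(n, sep = 10, seed = 1) {
  set.seed(seed)
  lab <- sample.int(2, n, replace = TRUE)
  centers <- rbind(rep(0, 5), rep(sep / sqrt(5), 5))
  X <- centers[lab, ] + matrix(rnorm(n * 5), n, 5)
  f <- as.data.frame(X)
  names(f) <- c("mean_speed", "sinuosity", "path_length",
                "lateral_speed", "longitudinal_speed")
  f$phase <- "2"
  list(features = f, labels = lab)
}

# straight constant-speed trajectory along +y
straight_trajectory <- function(speed = 0.5, duration = 10, rate = 50,
                                x0 = 0.2, y0 = 1, phase = "2") {
  tms <- seq(0, duration, by = 1 / rate)
  trajectory(tms, rep(x0, length(tms)), y0 + speed * tms,
             phase = phase, rate = rate)
}

default_radar_quiet <- function(...) radar_config(noise_sigma = 0, ...)
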