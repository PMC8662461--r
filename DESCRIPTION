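Package: ovitrack
Title: Radar-Based Tracking and Behavioural Phenotyping in Arena Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for millimetre-wave FMCW
    radar tracking of a single sheep in a standard arena test. Synthesizes
    ground-truth trajectories, radar range-azimuth frames and static
    clutter scenes; recovers the 2D trajectory by clutter normalization
    (per-cell background standardization) and per-frame peak detection;
    and computes behavioural estimators from the trajectory: 1-s window
    movement features classified by Gaussian mixture models with AIC
    selection, Ricker-wavelet transition counts per axis and phase,
    occupancy heatmap scores on an 80-zone grid, proximity and crossing
    scores over seven virtual areas, and a correlation-matrix PCA of the
    per-animal feature set with Kaiser-Guttman retention.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mclust,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
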