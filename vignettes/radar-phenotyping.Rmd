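---
title: "Radar tracking and behavioural phenotyping in the arena test: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radar tracking and behavioural phenotyping in the arena test: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovitrack)
```

## The problem

Standardized arena (pen) tests are used in sheep breeding programmes to score
social motivation: a focal lamb is placed in a 2 m x 7 m pen with three
conspecifics behind a grid barrier at the far end, and its movements are
recorded over three phases — 15 s of exploration with visual contact, 60 s of
social isolation behind an opaque panel (phase 2), and 60 s with the
conspecifics visible again and a motionless human present (phase 3). Manual
scoring limits throughput; `ovitrack` implements a tag-free alternative: a
millimetre-wave FMCW radar at the entrance end recovers the animal's 2D
trajectory, and a set of automatic estimators summarises its behaviour per
phase. Because no public recordings accompany the protocol, the package also
ships a full synthetic-data generator, so every stage is testable end to end
without any external input.

## Radar model and tracking

**Signal model.** The radar transmits a saw-tooth frequency-modulated chirp
(carrier 77 GHz, bandwidth B = 3 GHz, ramp 256 us indoors; 24 GHz / 800 MHz
outdoors). A point reflector at range $r$ returns a beat tone at
$f_b = 2 B r / (c\,T_{ramp})$; across the MIMO virtual array
($4 \times 8 = 32$ channels at half-wavelength spacing) its phase advances by
$2\pi d \sin\theta/\lambda$. `synthesize_beat_signal()` implements exactly
this model plus circular Gaussian receiver noise; `frame_to_map()` converts a
frame to a range-azimuth magnitude map by a Hann-windowed 2D FFT (Hann on
both axes for sidelobe control; the angle axis zero-padded to `n_angle_bins`
and expressed in $u=\sin\theta$, the natural beamforming grid). Range bin k
is centred at $k\,c/(2B)$ — bin width 5 cm at 3 GHz, the theoretical range
resolution returned by `range_resolution()`. A map-level shortcut
(`synthesize_map()`, separable Gaussian point spread of one-bin FWHM plus
complex noise taken in magnitude) lets downstream stages be tested without
the DSP in the loop; both synthesis routes agree on the argmax cell for a
noiseless target.

**Clutter normalization.** The pen walls backscatter far more power than the
sheep. With the animal absent, the per-cell time mean and standard deviation
of the map amplitude are estimated (`estimate_clutter()`, at least two
frames; the recording length is not prescribed by the protocol, sessions
default to 120 background frames). Each scene frame is then standardized
cell-wise:

$$D(t, r, \theta) = \frac{S(t, r, \theta) - \mathrm{mean}(r, \theta)}
{\mathrm{std}(r, \theta)}.$$

Zero-variance cells are guarded by `eps = 1e-12` in amplitude units (the
statistic is otherwise undefined there). On pure background, D has mean 0 and
unit standard deviation by construction, which the tests verify over 1000
simulated frames.

**Detection and track assembly.** Detection uses the global argmax of D per
frame with a threshold (default D >= 5; exposed as an argument since no peak
rule is prescribed — on pure background at the default grid this leaves a
small per-frame false-alarm rate that the detection-probability test
quantifies). Exact ties break towards the smaller range bin, then the
smaller angle bin, so results are reproducible. The peak is refined by
3-point parabolic interpolation along each axis — bin centres alone cannot
deliver cm-scale precision at a 5-cm grid. `assemble_track()` converts polar
fixes to arena coordinates (radar at the origin, boresight along +y, x
positive to the left facing down-arena, 0-based bins with bin value = cell
centre), fills gaps of invalid frames by constant-velocity linear
interpolation between flanking fixes, holds leading/trailing gaps at the
nearest fix, and clamps (and flags) out-of-arena fixes.

## Synthetic sessions

`simulate_trajectory()` is a Markov-switching correlated random walk. The
default `sheep_movement_model()` has four latent modes mirroring the
behavioural classes the mixture analysis recovers — slow (~0.05 m/s), fast
(~0.8 m/s), and tortuous variants of each (high turning volatility) — with a
sticky transition matrix whose stationary distribution weights the plain
slow/fast modes heavily and the tortuous modes lightly, as observed in real
cohorts. Speeds are per-sample truncated normals; headings random-walk with
per-step standard deviation `turn_sd * sqrt(dt)`; walls reflect. The frame
rate defaults to 50 Hz: the radar's processing tables state 50 measures per
second, although the printed 50-ms chirp repetition interval would imply
20 Hz — the rate is configurable and the discrepancy is simply noted here.

`generate_session()` draws per-animal docility and sociability scores and
couples them log-linearly to the propensities of the moving states:
sociability increases movement, docility decreases it (phase 2), and phase 3
multiplies the moving-state propensity by `phase3_activity` (default 0.35,
i.e. marked suppression of movement when the conspecifics are visible and a
human is present). The couplings re-target the chain's stationary
distribution via a softmax, preserving its stickiness — the simplest
monotone link that reproduces the reported effect directions. Infrared
beam-crossing events are derived from the ground truth at the six 1-m
boundaries. What the generator does **not** emulate: body extent and
micro-Doppler (the sheep is one point reflector), multi-animal scenes,
occlusions, bleats, and any real covariance structure between docility and
sociability (drawn independently). Passing tests therefore demonstrate the
estimators' correctness and sensitivity under the stated movement model, not
performance on real radar returns.

## Behavioural estimators

**Window features and movement classes.** Trajectories are cut into 1-s
windows within each phase (a trailing partial window shorter than 0.5 s is
dropped). Each window yields mean speed, sinuosity (path length over net
displacement), total path length, and the mean magnitudes of the lateral (x)
and longitudinal (y) per-step speed components — the speed vector is split
because the conspecifics sit at one end of the corridor. Sinuosity is
guarded as `max(path, floor)/max(net, floor)` with floor = one range bin
(0.05 m): the raw ratio diverges for closed loops and is 0/0 for a
stationary window, which the guard maps to exactly 1. Windows are
standardized and fitted with full-covariance Gaussian mixtures for k = 1..15
(`fit_movement_classes()`), selecting the k with the lowest
AIC = 2p - 2 log L. Two numerical choices matter here. First, each k is
fitted with 10 initializations (deterministic hierarchical agglomeration
plus random-agglomeration restarts, best log-likelihood kept): a single
deterministic initialization reliably misses rare classes of a few percent
occupancy. Second, a conjugate prior (`mclust::priorControl()`, with a
ridge-regularized scale matrix because full 1-s windows make path length and
mean speed exactly collinear) regularizes the covariances; without it,
unpenalized full-covariance EM reaches degenerate likelihood spikes and the
AIC curve decreases indefinitely. Even so, AIC is known to over-split large
mixture components; the package therefore reports and tests class structure
at the level of *semantic* classes: each component is named slow/fast x
plain/tortuous from its mean, and components falling in the same quadrant
pool. The naming thresholds are the pooled medians with absolute floors
(fast above `max(median speed, 0.25 m/s)`; tortuous above
`max(median sinuosity, 2)`). The floors are biologically grounded — 0.25 m/s
sits between a grazing shuffle and a walk, sinuosity 2 means the path is
twice the net displacement — and make the labels well defined when a cohort
has no genuinely fast or tortuous windows, where a bare median would split a
single cloud by sampling noise. `fast_movement_proportion()` is
fast/(slow + fast), ignoring the tortuous classes. Fitting is per animal by
default in single-animal workflows; `cohort_phenotypes()` pools windows
across the cohort (one mixture, comparable labels), fitting on a seeded
subset above 3000 windows and classifying the rest with the fitted model.

**Wavelet transition counts.** Changes in the way of moving are counted by
filtering each raw position coordinate with Ricker (Mexican hat) kernels —
zero-mean, unit-L2, support 8 scales wide, so constant and linear motion are
annihilated and an isolated velocity change produces a single
Gaussian-shaped ridge across scales. The default scale set is 8 log-spaced
scales from 0.2 s to 2 s: the response to a velocity kink grows as
$a^{3/2}$, so each change peaks at the top scale, and a 2-s top scale
resolves changes a few seconds apart while its boundary margin (one kernel
half-support, 4a, eroded from each phase edge) still leaves most of a 60-s
phase observable — scales of several seconds would merge neighbouring
changes and erode nearly the whole phase. A transition is a strict local
maximum of |coefficients| over its 8 neighbours in the scale x time plane
(plateaus count once, at their first position in scale-major order) whose
height reaches `rel_threshold` (default 0.1) of the field maximum. Within
`transition_features()` the threshold reference is shared across the
analysed phases per axis, so a phase with suppressed movement genuinely
counts fewer transitions rather than being re-normalized against itself.
Counts are reported per axis (x lateral, y longitudinal — fixed once here)
and per phase.

**Occupancy, proximity, crossings.** The arena is tiled into 16 x 5 = 80
lamb-sized zones (0.4375 m x 0.40 m by default). A visit is a maximal run of
consecutive samples in one zone, split at phase boundaries; the heatmap
score counts zones with a single continuous visit longer than 200 ms
("remained in" read as continuity — a cumulative variant is available by
flag, and the 1-s threshold used in some cohort models is just
`threshold = 1`). Cells and the seven 1-m virtual areas are half-open,
closed at the far (conspecific) edge. The proximity score weights per-area
dwell time by 1..7 (7 at the grid barrier; the weighting direction is
prescribed, the values are the simplest linear choice and configurable). The
crossing rate counts area-index changes sample to sample (a k-boundary jump
counts k), and `infrared_events()` emits the equivalent beam-crossing
events, which reconstruct the crossing count exactly.

**Phenotype assembly and PCA.** Per animal, eight features enter the
phenotype: fast-movement proportion, wavelet-X count, wavelet-Y count and
heatmap score, each for phases 2 and 3. Features are z-scored across the
cohort (at least 3 animals; zero-variance features are dropped with a
warning) and decomposed by a correlation-matrix PCA — the features have
incommensurate units, so covariance PCA would be dominated by the wavelet
counts. Loadings are sign-fixed so each component's largest-magnitude
loading is positive; components with eigenvalue strictly greater than 1 are
retained (Kaiser-Guttman; an eigenvalue of exactly 1 is not retained).
Reported variance fractions are eigenvalue/sum(eigenvalues).
`covariate_association()` regresses each component score on each covariate
by OLS — the tidy table that downstream mixed-model analyses (explicitly out
of scope here) start from; `pearson_agreement()` provides the
tracker-agreement correlations.

## Problem sizes used by the tests and acceptance script

The test-bed sizes are the package's own choices: 20 noiseless positions for
end-to-end recovery; 1000 frames (plus 500 for estimation) for the
background-standardization check on a 32 x 16 grid; 20 seeds x (400-window
two-mode, 800-window four-mode) plantings with k = 1..6 for class recovery;
20 seeds of 5- and 10-switch planted tracks for the wavelet counts; and 20
replicate 58-animal cohorts at the full three-phase protocol and 50 Hz for
the cohort-level checks (mixture scan k = 1..5, 3 restarts, subset cap 1500
windows there). The latent-chain goodness-of-fit test thins the chain to
approximately independent draws before applying the chi-square test, since
raw per-step occupancy counts of a sticky chain are strongly autocorrelated
and the unadjusted test would reject regardless of correctness.

## Known limitations

The tracker is single-target by design (global argmax; no data association
or CFAR variants), so a second mover in the scene would corrupt the track —
the outdoor two-target situation is representable only in map-level
fixtures. The azimuth resolution of the real antenna is not modelled beyond
the uniform-array beamforming grid. Mixture class counts selected by AIC
should be read through the semantic-class lens discussed above. All
cohort-level effect sizes produced by the generator are illustrative
plantings, not estimates of real sheep behaviour; the package deliberately
stops at the model-ready feature tables and does not refit the published
mixed models.
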