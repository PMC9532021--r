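---
title: "Methods: sample-based free-viewing analysis under nystagmus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-based free-viewing analysis under nystagmus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freegaze)
```

## Why sample-based analysis

Standard free-viewing pipelines segment gaze into fixations and saccades and
analyse fixation locations. In observers with nystagmus — continuous,
involuntary oscillation of the eyes — velocity/acceleration thresholds cannot
delimit fixations at all, so `freegaze` analyses *every* eye-tracking sample
(500 Hz), including high-velocity ones. All statistics below are therefore
defined on raw gaze samples, which also makes them uniform across
fixation-stable and nystagmic groups (labels used throughout: SC sighted
controls, DC developmental-cataract, CC congenital-cataract reversal, NC
idiopathic nystagmus).

## Geometry and data model

A `geometry_spec()` fixes the sampling rate (500 samples/s), the angular
resolution (pixels per degree; 800 px / 19.6° ≈ 40.8 px/° by default), image
extent and screen size. Gaze is stored in 0-based image-pixel coordinates
(origin top-left, y downward). Off-image samples and pupil losses are *kept*
and flagged invalid, never deleted: the missing-data fraction and the
inclusion rule (≥ 50 % valid samples per 4 s exploration,
`validity_filter()`) are only computable when missingness is represented.
Uncalibrated recordings may be constructed with `space = "raw"`, which
suspends the image-bounds check until `apply_calibration()` maps them into
image space.

## Calibration

Five targets (centre, ±15° horizontal, ±8.5° vertical) are each associated
with experimenter-selected low-velocity gaze windows (in nystagmus these
follow the corrective fast phase). Per-target medians are computed first, then
a full quadratic in the raw coordinates (6 coefficients per axis) maps raw to
screen positions. With five targets the quadratic is underdetermined; we solve
by minimum-norm least squares on a centred, scaled design (SVD, singular
values below 1e-10 of the maximum dropped). Centring on the target cross has a
useful consequence: the only free direction is the cross term, which is
orthogonal to any affine map, so an affine tracker distortion is recovered
*exactly everywhere*, not merely at the targets. Calibration error is
reported only at the central target (`central_error()`), in degrees, as the
distance between the calibrated window median and the screen centre.

Window selection itself is taken as given input: it was a manual,
expert-judgement step in acquisition and cannot be faithfully automated from
a description; the simulator emits such windows directly.

## Instantaneous gaze velocity

`instantaneous_velocity()` implements the smoothed two-point central
difference used as the default by video eye trackers:

$$v(n) = \mathrm{SR}\,\frac{g(n{+}4)+g(n{+}3)+g(n{+}2)-g(n{-}2)-g(n{-}3)-g(n{-}4)}{18\,\mathrm{PPD}}$$

per axis, in °/s; 18 is the sum of the index differences. No additional
smoothing is applied — the six-sample sum is the noise filter. The operator is
exact for trajectories linear in the sample index, which the tests exploit as
an oracle. A sample's velocity is *defined* only when its ±4 neighbourhood is
entirely valid; samples adjacent to missing data are flagged undefined, never
interpolated or zeroed (the original analysis does not state a rule; flagging
is the conservative choice and keeps every downstream statistic explicit
about its support). Velocity-magnitude deciles (`velocity_quantile_partition()`,
ties broken by sample order for determinism) feed the foveation analysis.

## Exploration entropy

Valid samples are binned into a 20×20 grid over the image
(`grid_counts()`, half-open cells, the terminal edge folded into the last
cell so no sample is lost). `coverage_adjusted_entropy()` reports

$$H = \frac{-\sum_i p_i \log_2 p_i}{\hat C}, \qquad \hat C = 1 - N_1/N,$$

the plug-in Shannon entropy divided by the Good–Turing sample-coverage
estimate ($N_1$ = cells gazed exactly once), which counteracts the downward
bias of the plug-in estimator at 4 s of data. Two grouping choices deserve
note. First, the division by coverage is applied to the summed entropy — a
scalar correction for unobserved support; a per-summand division has no
estimator-theoretic basis. Second, the 20×20 cell *count* is taken as
authoritative (cells of 40 px ≈ 0.98°): a literal "2° cell" tiling cannot
cover a 19.6° image with 20 cells. $\hat C$ is floored at $1/N$ so the
all-singletons case stays finite. Robustness grids are 40×40 and 10×10
(`entropy_robustness()`); the tests check that concentrated vs dispersed
recordings keep their entropy ordering across all three resolutions, which is
the property the original robustness check relies on.

## Predictor maps

Three families, all sum-normalised nonnegative per-pixel maps
(`predictor_map`):

* **Empirical** (`empirical_map()`): pixel-level valid-gaze counts pooled
  over the contributing (typically SC) participants, smoothed with a unit-sum
  Gaussian kernel of FWHM 2° (σ = FWHM/2.3548 · PPD), normalised. For
  within-group prediction the scored participant is excluded
  (leave-one-out); the exclusion contract is tested by perturbing the
  excluded participant's data.
* **Luminance contrast** (`contrast_map()`): Gaussian-weighted local standard
  deviation of intensity, then the same FWHM-2° smoothing. This is a simple
  low-level feature map standing in the same slot where a trained
  intensity-contrast model would sit; externally computed maps (e.g.
  deep-network saliency) enter through `load_external_map()` and are treated
  identically downstream.
* **Low-pass variants** (`lowpass_image()`): Gaussian blur parameterised by
  the frequency at which its modulation transfer falls to 0.67 — at cutoff
  period $c$ degrees, $\sigma_\deg = c\sqrt{\ln(1/0.67)}/(\pi\sqrt2)$. This is
  the only reading of a "frequency cutoff (reduction, 0.67)" that yields a
  concrete kernel, and it is verified in the tests by measuring the
  attenuation of a pure grating at the cutoff frequency.

All convolutions use separable FFT convolution with reflect padding (no mass
leakage at borders; a constant field stays constant to < 1 % right up to the
edge). Kernels are truncated at 4σ and renormalised to unit sum.

## Bias-controlled AUC

The central statistic asks: do a map's values classify locations a
participant gazed at versus locations they did not? Crucially, "nongazed"
locations are not random pixels — they are the *same participant's gaze
locations on other images* (`sample_nongazed_values()`), so both classes
share the center bias of human gaze and of photographic composition, and
AUC > 0.5 indicates image-specific prediction. We draw as many nongazed as
gazed samples, without replacement where the pool allows (flagged otherwise);
the draw for each (participant, image, trial, partition) is a pure function
of the master seed, so different map families are scored against the
identical null sample and paired comparisons are meaningful.

`auc_from_values()` uses the rank-sum form with midranks for ties:
$U = R_{gazed} - n_g(n_g+1)/2$, $\mathrm{AUC} = U/(n_g\,n_{ng})$; a
brute-force pair-counting oracle (with half-credit ties) pins it to 1e-12 in
the tests. Pooling is per participant across images
(`auc_per_participant()`) or per image across participants
(`auc_per_image()`). Controls and decompositions:

* `shuffled_control()`: a seed-controlled derangement reassigns maps to
  images (no image keeps its own); a map-driven cohort drops to chance.
* `time_binned_auc()`: eight 500 ms intervals; the nongazed pool is
  restricted to the *matching* interval of the other images. Interval
  matching is what makes the first-interval control meaningful: with enforced
  central trial starts both classes are central early on, so interval-1 AUC
  sits at chance while later intervals reflect map-driven exploration.
* `velocity_binned_auc()`: participant-specific velocity-magnitude deciles;
  nongazed pools are whole-trial (no velocity matching is implied by the
  design). This probes whether prediction is confined to slow, foveation-like
  phases of the nystagmus cycle.

## Repetition (short-term memory) and group statistics

`build_repetition_table()` joins entropy results to the trial structure
(7 identical-repeat, 7 same-category, 14 different-category pairs per
session); pairs with either member discarded by the validity filter are
dropped entirely, because the within-pair contrast is undefined for
half-pairs. `repetition_contrast()` fits
`H ~ group + image_order + (1 | participant)` per pair type.

`robust_group_contrasts()` fits the per-participant statistic on the group
factor by IRLS with Tukey's bisquare (c = 4.685, the conventional 95 %
Gaussian-efficiency constant) and tests all six pairwise contrasts at
0.05/6. `mixed_model()` delegates to lme4 with lmerTest's Satterthwaite
degrees of freedom; a singular random-effect fit is flagged and reported as a
fixed-effects-only fallback with residual df, so the df provenance is always
explicit in the output. `recognition_model()` fits binomial-logit models of
per-image naming correctness on acuity (logMAR), AUC, and both, compared by
AIC and Tjur's discrimination coefficient; separation is detected and handled
by a lightly ridge-penalised logistic fit, clearly flagged. Recognition is
modelled at the image level with participant-level predictors — the
finest-grained reading of per-image correctness flags.

## The synthetic cohort generator

`generate_images()` produces grayscale stimuli with a textured object region
near the centre and a ground-truth attention map: a mixture of 2–5 isotropic
Gaussians (component centres within the central half of the image, σ between
0.7° and 1.5°) whose analytic parameters travel with the map so tempering is
exact. `simulate_recording()` draws a target sequence from
$\mathrm{map}^{1/(\tau\cdot d)}$ (fidelity τ, dispersion d; identical repeats
use exponent c, the concentration factor) and renders it at 500 Hz:

* *fixation_saccade* (SC/DC-like): dwells of 300 ± 60 ms joined by 30 ms
  transitions, with smooth AR(1) fixational jitter (stationary SD 0.15°).
* *horizontal_jerk* (NC-like): the same target process (dwell 600 ms — slower
  retargeting, as seen in nystagmus) plus a horizontal beat: an accelerating
  slow-phase drift away from the target (exponential velocity growth, rate
  2.5) and a fast corrective reset, 4° at 4 Hz. Low velocities therefore
  coincide with on-target (foveation-like) positions, giving the
  velocity-binned analysis its ground truth.
* *multiplanar_irregular* (CC-like): the same beat at 3° / 3 Hz with a random
  direction each cycle.

These parameters were calibrated once so the generated kinematics reproduce
the qualitative contrasts the analysis is meant to detect — median velocity
ordering fixation < multiplanar < jerk, and a horizontal/vertical velocity
variance ratio above 3 for the jerk profile only — and are not adjusted
thereafter. Missing data are inserted in runs (mean 100 ms) at group rates
taken from the study populations (CC 10 %, SC 3.7 %, DC 4.3 %, NC 10 %);
trials start with 500 ms anchored at the image centre. Acuity is drawn
uniformly within group-typical logMAR ranges (CC 0.5–1.4, DC 0.2–0.8,
NC 0.1–0.6, SC 0–0.2), a group-resolved refinement of the overall 0–1.4 span.
`simulate_session()` assembles the 2-block × 14-trial design over 49 images
(7 categories × 7) and draws naming outcomes from
`logistic(-2 - 3·acuity + 6·AUC_truth)` where `AUC_truth` is the
participant's AUC against the *ground-truth* maps — using the truth maps, not
estimated ones, avoids circularity in model-recovery tests.

What the generator does *not* emulate: photographic image statistics (its
contrast maps are only structurally, not visually, realistic), saccadic main
sequences and latencies, binocular disparity, smooth pursuit, blink
kinematics, or waveform taxonomy beyond jerk/multiplanar. Passing tests
therefore certify the pipeline's statistical machinery and its behaviour
under controlled kinematic regimes — not that any particular empirical effect
size in the original populations is reproduced.

## Numerical and inferential choices

* Tempered target sampling discretises the analytic mixture on a 100×100
  grid with within-cell uniform jitter (cells ≈ 0.2°, far below kernel
  scales).
* Coordinates are rounded to 0.001 px when written, so the text interchange
  format round-trips bit-exactly.
* All randomness descends from one master seed through a deterministic
  hash (`participant`, `image`, `trial`, `partition` labels), so every stage
  is a pure function of (inputs, config, seed) — verified by rerun-identity
  tests.
* Repetition specificity is judged directionally at the family-corrected
  level 0.05/3 (three pair-type models per cohort), in keeping with the
  Bonferroni practice used for the group contrasts; an uncorrected two-sided
  criterion would by construction flag ~5 % of null pair types per family.
* Problem sizes used in the shipped tests: unit tests run on a reduced
  196-px geometry (same angular extent); the study-condition checks use the
  full 800-px geometry with 12-participant, 28-trial cohorts over 20 seeds —
  the same sizes the acceptance script simulates.

## Known limitations

* The coverage estimator and the polynomial order of the original
  calibration are cited, not specified, in the source; Good–Turing and the
  centred quadratic are documented stand-ins with the stated properties.
* Empirical maps at pixel resolution are memory-heavy (one double per pixel
  per image); for very large stimulus sets compute maps per image on the fly.
* The shuffled control sits ~0.01 below 0.5 on map-driven cohorts: under a
  derangement the nongazed pool still contains gaze from the image whose map
  is being used, slightly enriching the null with high-map locations. This is
  a property of the design, shared with the original procedure, and well
  inside the chance band.
* `velocity_binned_auc()` requires ≥ one defined-velocity sample per decile
  per participant; heavily missing recordings can abort the partition (the
  pipeline surfaces this as a stage error rather than silently dropping
  deciles).
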