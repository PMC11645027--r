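---
title: "Methods: instrumented sit-to-stand assessment of locomotive syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrumented sit-to-stand assessment of locomotive syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locomo)
```

## The problem

Locomotive syndrome (LS) is the age-related decline of locomotor
function that puts older adults at risk of losing independent mobility.
It is staged from the GLFS-25 self-report questionnaire (25 items, each
0–4): below 7 points is non-LS, 7–15 is stage 1, 16 and above is stage
2 (`assign_stage()`). The five-time sit-to-stand test (FTSTS) — rising
fully from a 40 cm chair and sitting back down five consecutive times,
arms folded, at a self-selected pace — stresses exactly the lower-limb
strength and postural control that LS erodes. A single inertial
measurement unit (IMU) at the lumbar spine turns that test into a rich
kinematic signal, and this package turns the signal into a staged
classification.

## The synthetic cohort generator

Real recordings of this kind are rarely shareable, so the package
ships a generator that produces cohorts with the statistical structure
the analysis depends on, plus exact ground truth. Each sit-stand-sit
cycle is built from a smooth pitch-angle profile — a sum of logistic
ramps, forward flexion followed by extension at each postural
transition — whose analytic derivative gives the pitch angular-velocity
channel: one dominant negative trough (peak magnitude
`peak_pitch_velocity`, deg/s) per transition, two per cycle. The AP and
SI acceleration channels carry time-locked bursts (an odd biphasic
shape and an even "braking" bump, scaled by `peak_ap_accel` and
`peak_si_accel`, m/s²); the ML channel is low-amplitude postural sway
whose frequency is drawn per participant from 0.3–0.5 Hz, so that no
spectral feature is artificially identical across a cohort. Gaussian
noise of standard deviation `tremor_noise_sd` (m/s²) is added to the
accelerometer channels and, scaled ×10 into deg/s, to the gyroscope.
Per-cycle durations are log-normal with configurable mean and CV, and
seat-off / seat-on times are recorded as ground truth.

Accelerations are generated gravity-free, since zero-centering removes
constant offsets anyway; `gravity_offset = TRUE` adds 9.81 m/s² to the
SI channel to exercise that step.

The class-conditional defaults (`kinematic_params()` presets) order the
groups so that a higher stage means slower, weaker, noisier movement:

| group | cycle (s) | CV | pitch trough (deg/s) | AP peak (m/s²) | SI peak (m/s²) | noise SD (m/s²) |
|---|---|---|---|---|---|---|
| Young  | 1.5 | 0.06 | 90 | 2.4 | 2.0 | 0.03 |
| NonLS  | 1.8 | 0.08 | 75 | 2.0 | 1.6 | 0.05 |
| Stage1 | 2.4 | 0.10 | 60 | 1.5 | 1.2 | 0.08 |
| Stage2 | 3.0 | 0.12 | 45 | 1.1 | 0.9 | 0.10 |

**These are configuration values, not measurements.** They were chosen
once to create plausibly separable classes; no per-class kinematic
statistics were available to calibrate them against a real population.
`generate_cohort()` jitters each participant's magnitudes around the
preset by a multiplicative log-normal factor (`between_subject_cv`,
default 0.06), draws GLFS-25 scores uniformly within each stage's
interval (only the cut-offs matter downstream), and takes sex ratios
and age distributions from the published demographic summary of the
cohort composition it emulates (47 / 29 / 49 / 49 participants).

Because the classes are separable by construction, classification
results on synthetic cohorts demonstrate that the pipeline *recovers
structure that is present*; they say nothing about how much structure
real FTSTS recordings contain. The generator also does not emulate
sensor dropout, orientation drift, failed rises, or the heavy-tailed
variability of real tremor.

## Preprocessing

`preprocess_recording()` applies, in order: per-channel zero-centering
over the whole recording; resampling to `target_rate_hz` (default
50 Hz); and a Butterworth low-pass of order `filter_order` (default 3)
at `cutoff_hz` (default 5 Hz, well above the < 3 Hz band of sit-to-stand
kinematics). Filtering is zero-phase (forward–backward) by default:
event *timing* drives segmentation, and a causal 3rd-order filter would
delay the pitch troughs by tens of milliseconds. `zero_phase = FALSE`
restores the literal single-pass filter (at double the nominal
attenuation's cost). Forward–backward passes are wrapped in odd
reflection padding, which suppresses the start-up transients that plain
`filtfilt` leaves at the signal edges.

Resampling filters with a zero-phase 8th-order Butterworth anti-alias
filter at 90% of the new Nyquist frequency and then interpolates with a
cubic spline at the new timestamps. This is delay-free and exact to
well below 1e-3 for band-limited signals; a polyphase FIR resampler was
rejected because its group delay would have shifted event times.
Ground-truth event times are carried as seconds, not sample indices, so
they survive resampling unchanged.

## Segmentation

Forward trunk flexion produces a trough in the gyroscope pitch
angular velocity at every sit-to-stand *and* stand-to-sit; these
troughs are the segmentation cue. The pitch channel of a gyroscope
already measures change of angle, so the trace itself is used;
`differentiate = TRUE` supports the alternative reading (first
derivative of an integrated pitch angle). Candidate strict local minima
are ranked by topographic prominence — walk outward from the trough to
the first lower sample on each side, take the smaller maximal excursion
— and kept if prominence exceeds `min_prominence` (default 20 deg/s,
conservative against the 45–90 deg/s troughs of self-paced FTSTS).
Troughs closer than `min_separation_s` (default 0.5 s) are thinned to
the more prominent one.

Minima are paired into cycles by alternation starting with a
sit-to-stand. Each transition window extends outward from its trough
until the absolute pitch velocity falls below `boundary_fraction`
(default 0.1) of the trough magnitude, capped at the midpoint to the
neighbouring event. The SSS window of cycle *k* spans its SiSt start to
its StSi end; the FTSTS window spans the first SiSt start to the last
StSi end. Windows are 1-based inclusive index ranges. An odd trailing
event is dropped with a warning; no events at all is an error naming
the recording. A flat trace yields an empty detection, not an error.

## The 144-metric feature set

Nine metric families × four channels (ML, AP, SI, resultant) × four
contexts (FTSTS, SiSt, StSi, SSS) = 144 named metrics,
`{context}_{channel}_{metric}`. For the repeated contexts the
per-repetition values are averaged; their coefficients of variation
(sample SD over |mean|) are attached as `cv_`-prefixed supplements —
108 of them — rather than counted among the primary 144. A CV is
undefined (`NA`), never NaN, for a single repetition or a zero mean.

Two families — duration and the resultant maximum `AMax` — do not
genuinely vary by channel; they are replicated across channels so the
canonical 4 × 4 × 9 count holds exactly. `layout = "compact"` keeps one
copy per context (120 metrics) for users who prefer no replication.
Whether the original 144 included CV terms instead of some means is not
decidable from the available description; this package exposes both
layouts and defaults to the replicated one.

Numerical choices in the spectral metrics: segments are zero-padded to
the next power of two (fast, deterministic bin grid), not windowed; the
spectrum is one-sided with the DC bin excluded, since segment-level
residual offsets carry no movement information after recording-level
zero-centering. The spectral edge frequency is the smallest bin
frequency at which the cumulative power reaches the requested fraction,
with a 1e-9 relative tolerance so an exact 50/50 power split lands on
the lower edge. SEF of a zero-power signal is an error, as is any
non-finite feature value (reported with its context/channel/metric
name). Jerk follows the printed convention of summing squared
consecutive sample differences over the window duration `T` without an
inner division by the sample interval; its units are therefore m²/s⁵
at 50 Hz, and values are comparable only within a fixed sampling rate.

## Classification stack

`run_modeling()` drops the `cv_` supplements (the primary 144 are the
feature set), then applies:

- **SMOTE** (`smote_balance()`): minority classes grow to the majority
  count with synthetic rows `x + u (x_nn − x)`, `u ~ U(0, 1)`, between a
  class member and one of its `k = 5` same-class nearest neighbours.
  Originals are preserved verbatim; the result is deterministic under
  the seed.
- **Stratified split** (`split_cohort()`): `ceiling(0.2 n_class)` test
  rows per class, seed 42 by default.
- **Z-scoring** (`zscore_transform()`): means and sample SDs fitted on
  the training rows only and applied to the test rows, so no test
  statistic leaks into training. Constant columns are dropped with a
  warning.
- **Reduction**: PCA (`pca_reduce()`) keeping the smallest component
  count whose cumulative explained variance reaches `pca_variance`
  (default 0.95 — the original component count was never stated, so
  reports flag the retained count prominently), or mutual-information
  selection (`select_k_best_mi()`, default top 40). The MI score is a
  plug-in estimate with equal-frequency binning (10 bins) and a tiny
  seeded jitter to break ties between duplicated values — a pragmatic
  estimator chosen because no nearest-neighbour MI implementation is
  among the package's dependencies; for ranking ~150 features against a
  4-level label it is entirely adequate.

**Ordering.** The published description of this kind of pipeline is
internally inconsistent: the balancing and PCA steps are described as
applied to the whole dataset around the split, while the normalization
step is explicitly motivated by preventing test-to-train leakage. The
default here is the leak-free order (split → SMOTE on train → scale on
train → reduce on train); `whole_data_order = TRUE` reproduces the literal
whole-dataset ordering (SMOTE before splitting, PCA fitted on the
pooled rows) so the discrepancy can be explored. The two orders are
compared in the test suite.

Classical families run behind one `fit_classifier()` surface: SVM
(linear and RBF, e1071), KNN (stored-training neighbours with uniform
or distance-weighted votes — implemented here because distance
weighting is the tuned configuration and no dependency provides it),
decision tree (rpart; its depth cap is 30, so deeper grid values are
clamped), random forest (ranger; `max_depth = NA` maps to unlimited
depth, `bootstrap = FALSE` to sampling without replacement), gradient
boosting (xgboost; `min_samples_split` has no direct analogue and maps
onto the child-weight control), and L1/L2 multinomial logistic
regression (glmnet; `lambda = 1 / (C n)`). `grid_search_train()` scans
the full cartesian grid by stratified cross-validated accuracy
(default 5 folds — the original fold count is unstated), breaking ties
by first-in-grid order, then refits the winner.

The **funnel MLP** (`mlp_train()`) is implemented directly in R matrix
operations: dense layers 512-256-128-64-32, ReLU activations, softmax
output over one-hot labels, cross-entropy loss with L2 weight decay
(default 0.001), He initialization, mini-batch Adam (learning rate
0.001, batch 64, up to 200 epochs), and early stopping on a stratified
10% validation split with patience 20 (both unstated in the original
description; these are conventional values). At these layer widths and
cohort sizes a training run is a few seconds of BLAS work, and training
is bit-reproducible under a fixed seed.

`evaluate_model()` reports the confusion matrix (rows true, columns
predicted), accuracy (trace over total), and per-class precision,
recall and F1 aggregated as `weighted` (default, by true-class support)
or `macro` — the original averaging convention is unstated. Classes
absent from the test set or never predicted are zero-division guarded
and flagged. `tidy()` and `glance()` give per-class and one-row views;
`autoplot()` draws the confusion matrix.

## Reproducibility and problem sizes

Every stochastic operation takes a seed, and cohort-level seeds are
derived deterministically per participant and stage from the single
global seed, so `run_pipeline()` is bit-reproducible end to end. The
test suite exercises full 174-participant cohorts for the composition
and recovery checks, ~40-participant cohorts for pipeline plumbing, and
closed-form or brute-force oracles (direct DFT, exhaustive scans,
hand-computed confusion matrices) for every formula; the recovery
criterion averages the PCA+MLP test accuracy over five split/seed
replicates.

## Known limitations

- The generator's classes are separable by design; synthetic accuracy
  ceilings say nothing about real-world discriminability of LS stages.
- Jerk units follow the printed summation convention and are
  rate-dependent; cross-rate comparisons require re-normalization.
- The binned MI estimator is coarser than nearest-neighbour estimators
  for small samples; rankings of nearly tied features may differ.
- The decision-tree depth grid is clamped at rpart's depth cap of 30.
- Gyroscope-derived features (angular range, angular velocity metrics)
  and nonlinear-dynamics features are out of scope, as are orientation
  estimation and sensor-fusion preprocessing.
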