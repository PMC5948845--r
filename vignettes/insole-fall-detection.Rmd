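---
title: "Classifying falls from insole sensors: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying falls from insole sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A shoe-insole sensor system — one tri-axial accelerometer (±8 g) and four
force-sensitive resistors (FSRs), one per foot quadrant, sampled at 20 Hz —
streams seven channels per sample. The task is to decide, per 6-second
trial, whether the wearer fell or performed one of eight activities of
daily life (ADLs): walking, standing, lying, sitting, running, stair
ascension, stair descension, or jumping. The hard part is the
high-acceleration ADLs: running and jumping produce acceleration peaks
that look like falls to simple threshold detectors.

`insolefall` implements the full pipeline: signal model and calibration,
event-centered windowing, a 45-feature registry, a polynomial-kernel
multiclass SVM evaluated by leave-one-subject-out cross-validation
(LOSO-CV), genetic-algorithm (GA) wrapper feature selection, and a
synthetic protocol simulator that stands in for the original recordings,
which were never released.

## Signal model and windowing

The orientation-invariant *Sum Vector Magnitude* of the acceleration,

$$\mathrm{SVM}(t) = \sqrt{A_x(t)^2 + A_y(t)^2 + A_z(t)^2},$$

reads 1 g at rest in any posture and ~0 g in free fall. The *filtered*
magnitude passes this signal through a 1st-order low-pass Butterworth
filter with a 1 Hz cutoff, which suppresses brief gait transients while
preserving sustained unweighting: running stays above 0.9 g after
filtering, while stair climbing, jumping and falls dip below it.

Each trial is reduced to a single 121-sample window (6.05 s): the global
minimum of the filtered magnitude is located over the whole trial, and 60
samples (3 s) are taken on each side. For falls this minimum sits in the
free-fall/impact phase, so the window brackets the fall and its
aftermath.

Numerical choices worth knowing:

* **Phase mode.** Filtering is zero-phase (forward–backward) by default.
  A causal 1st-order filter at 1 Hz has ≈0.16 s of group delay, which
  would shift the located minimum off the event; zero-phase keeps it in
  place at the cost of doubling the effective order. Causal mode is
  available via `filter_spec(phase = "causal")`.
* **Edge handling.** The filter runs over an odd-reflection-padded signal
  with DC-matched initial conditions, so a constant signal passes through
  exactly and startup transients land in the padding, not the data.
  ADL streams are filtered as continuous streams *before* segmentation
  into trials, so trial windows keep their true context.
* **Ties and edges.** Equal minima break to the earliest index. Windows
  whose center is within 60 samples of a trial edge are shifted minimally
  to fit ("clamped") rather than padded — padding would fabricate sensor
  data. Indices are 1-based throughout, following R convention.

## The feature registry

`feature_registry()` enumerates the 45 candidate features per window:
per-axis and total-magnitude mean/variance/skewness/kurtosis (1–16),
spectral energies (17–20), axis-pair Pearson correlations (21–23), raw
and filtered magnitude extrema (24–27), the percent of the window with
filtered magnitude below 0.9 g (28), the filtered-magnitude variance over
the final 2 s (29), and per-FSR on-duration, on/off switch count, window
mean and final-2-s mean (30–45).

Conventions the registry freezes (the classifier only needs internal
consistency, but they are documented so numbers are reproducible):

* "Total acceleration" is the per-sample raw Sum Vector Magnitude — the
  only per-sample scalar magnitude available.
* Variance uses the unbiased (n−1) estimator; skewness and kurtosis are
  bias-uncorrected standardized moments, kurtosis reported as excess.
  Degenerate (constant) channels yield 0, not `NaN`, so feature matrices
  stay finite.
* Energy is the Parseval spectral energy excluding the DC term, divided
  by the squared window length — equivalently the mean squared deviation
  from the window mean. A sinusoid of amplitude *A* has energy *A²/2*.
* The sub-0.9 comparison is strict (`< 0.9`), as is the FSR on threshold
  (`> 100` of 4095 analog levels, so a residual-load reading of exactly
  100 counts as off).
* The "final 2 s" is the last 40 samples of the 121; the center sample is
  not part of the tail.

Features are computed on offset-calibrated accelerations
(`calibration_spec()`, default zero offsets); FSRs are used as raw analog
levels — force-unit calibration is unnecessary because only contrasts
(standing vs sitting, loaded vs unloaded) matter.

## Classifier and validation

`train_svm()` fits a one-vs-one multiclass SVM with a polynomial kernel
$(\gamma\,u^\top v + c_0)^d$, degree 3, $\gamma = 1$, $c_0 = 1$, cost 1 —
a standard default trio, exposed in `svm_config()`. Features are min-max
normalized to [0, 1] with parameters fit on the training fold only
(min-max rather than z-scoring because FSR features are bounded counts
and levels); test values may land outside [0, 1] and are not clipped.

`leave_one_subject_out_cv()` trains on all subjects but one and tests on
the holdout, once per subject. No information from the test subject —
including its normalization statistics — reaches training, and the fold
provenance is recorded so leakage is assertable. Fold predictions pool
into a 9×9 confusion matrix; `class_metrics()` computes one-vs-rest
sensitivity, specificity and accuracy per class. Display rounding is
half-up to 3 decimals; raw values are kept in the JSON report twin.
`reference_confusion()` embeds a published confusion table for this task
so the metric computations can be verified against printed values.

## GA wrapper feature selection

`ga_select()` evolves binary masks of the feature columns to minimize
`ga_fitness()`: fall false positives plus fall false negatives under
*subject-grouped* 5-fold cross-validation on the training subjects
(grouped folds keep the fitness honest about subject generalization; full
inner LOSO is available via `inner_folds`). The outer LOSO test subject is
excluded from fitness evaluation, so selection never sees validation
data. An all-zero mask receives the dataset size as penalty.

Published settings are kept: up to 1000 generations, 60-generation stall
limit, 0.8 crossover fraction, 0.01 per-gene mutation rate. What they
leave open is filled with common defaults: population 50, elite count 2,
stochastic-universal sampling on rank-scaled fitness ($1/\sqrt{rank}$),
uniform (scattered) crossover. One deliberate departure from the MATLAB
convention of disjoint crossover-only and mutation-only child pools:
mutation is applied to *every* non-elite child after crossover (the
canonical GA order). At reduced budgets — e.g. population 20 for 50
generations — the disjoint scheme explores only a couple of bit flips per
generation and stalls far from convergence; the canonical order makes the
small-budget runs used in testing converge while leaving the four
published numbers untouched. Elitism makes the best-fitness trace
non-increasing, and fitness values are cached per mask. Fitness ties are
resolved by GA dynamics only; no parsimony tie-break is applied.

`optimal_feature_mask()` ships the published 18-feature optimum;
`feature_set_masks()` adds the benchmark rosters (accelerometer-only,
FSR-only, combined, all 45) for `feature_set_comparison()`.

## What the simulator emulates — and what it does not

`generate_protocol_dataset()` reproduces the study conditions: 20
subjects, 2 minutes of each ADL segmented into 20 windowable trials
(121 samples spanning 6.000 s each, adjacent trials sharing one endpoint
sample — which reconciles the protocol's "six-second" segments with the
121-sample window), and 5 trials of each of 8 fall types, for 3200 ADL
trials, 800 falls and exactly 320 ADL minutes.

The generative model (see `activity_profiles()`) builds the magnitude
signal from a 1 g baseline, a cadence-locked sinusoid plus one harmonic,
activity-specific raised-cosine transients (stance unweighting on stairs,
flight phases when jumping, the free-fall dip/impact spike/ring-down of
falls), and white Gaussian noise; acceleration is this magnitude
projected on a slowly varying body-orientation vector (upright, reclined,
lying), which is what gives the per-axis features their class signal. FSR
channels follow per-activity load patterns: constant loaded (stand),
constant unloaded at ~45 of 4095 levels (sit/lie — deliberately below the
on threshold), cyclic gait with the heel leading, cyclic flight (jump),
and load-then-unload (falls). Subjects differ by log-normal (σ = 0.1)
multiplicative scales on cadence, amplitude and FSR baseline — the
magnitude of real between-subject deviation is unquantified, so this is a
package choice. Fall trials end in ≥2 s of static lying with the insole
unloaded, and stumble variants insert a >2 g transient before the fall.

The per-activity transient depths and widths were calibrated once against
the published per-activity mean percentages of the window below 0.9 g
(run 0.15 %, stair ascension 23.68 %, stair descension 14.60 %, jump
56.30 %, falls 13.35 %) and then frozen in `activity_profiles()`; the
simulated means land near those targets and reproduce the characteristic
ordering jump > stair ascension > stair descension > fall > everything
else.

What the simulator does *not* attempt: biomechanically faithful gait,
soft-tissue impact dynamics, elderly-specific fall kinematics, sensor
drift, or the full messiness of uncoached human movement. Its classes
are *more* separable than real recordings — the synthetic LOSO fall
sensitivity is ≈1.0 where the published figure is 0.996 — so passing
tests demonstrate that the pipeline machinery is correct and that the
features separate the signal structures they were designed for, not that
these exact error rates transfer to real subjects.

## The feature-selection benchmark

Because the protocol simulator's falls are so cleanly separable, adding
pure-noise columns costs the SVM no fall errors at all — measured, not
assumed — which would make a selection-recovery test vacuous. The
dedicated benchmark `simulate_feature_task()` therefore generates the
regime wrapper selection exists for: falls are heterogeneous, every
informative feature captures one *fall mode* (in the spirit of the real
registry, where distinct features capture the free-fall dip, the
post-fall stillness or the unloaded insole), so dropping any one hides a
mode; and `plant_noise_features(subject_scale_log_sd = 3)` plants
class-free noise channels that are quiet for most subjects but wild for
some — channels that actively hurt subject-grouped CV and should be
discarded. Defaults (8 subjects × 40 windows, mode effect 8 sd, fall
fraction 1/2) were fixed once so that every informative feature is
individually necessary and every noise feature measurably harmful; a
population-20, 50-generation GA then recovers ≈95 % of the informative
and keeps ≈23 % of the noise columns (5-seed averages, computed by the
test suite).

## Problem sizes used by the tests

The test suite exercises the full 20-subject protocol once (4000 trials;
generation plus featurization takes well under a minute) and reuses it
for the dip-fraction ordering, the protocol totals and the LOSO check
with the reference mask; classifier mechanics run on a 4-subject
miniature, and GA runs use the benchmark task at its default size with
population 20. These sizes are the package's choices for a thorough but
fast default suite; everything scales up through `protocol_config()` and
`ga_config()`.

## Known limitations

* The simulator's separability overstates real-world performance; treat
  synthetic LOSO numbers as pipeline verification, not clinical claims.
* The exact moment/energy conventions, SVM hyperparameters, GA
  population/selection scheme and inner-CV protocol of the original
  study are unrecoverable; the package freezes reasonable conventions
  and exposes them in configuration objects.
* One window per trial: continuous monitoring (sliding windows over an
  unsegmented stream) and real-time latency are out of scope.
* Non-fall specificity/accuracy footers of the embedded reference table
  are computed with the standard one-vs-rest formulas; for the non-fall
  classes these do not reproduce the originally printed footer values
  (whose formula is not recoverable from the published counts), so only
  the row-wise sensitivities and the fall-class specificity/accuracy are
  asserted against it.
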