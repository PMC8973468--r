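---
title: "Methods: pupillometric features, mixed models and wrapper selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupillometric features, mixed models and wrapper selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilload)
```

## The problem

Cognitive effort transiently dilates the pupil (the task-evoked pupillary
response). In a digit-span working-memory experiment, a participant fixates a
cross for 2 s (the *prestimulus* phase), then sees a sequence of digits, one
per second — 3, 5 or 8 digits for *low*, *medium* and *high* difficulty — and
must recall them. `pupilload` turns raw binocular pupil-diameter traces from
such an experiment into (i) per-trial features, (ii) per-feature statistical
tests of the difficulty effect, and (iii) a difficulty classifier selected by
exhaustive wrapper search.

The package ships a synthetic-data generator with the same experimental
structure, so every stage can be exercised, tested and benchmarked without
eye-tracker hardware or access to any particular recording.

## Preprocessing

Cleaning follows the conventional recipe for remote eye trackers:

1. records flagged invalid by the device, or with both eyes missing, are
   removed (the device validity codes stand in for blink detection; no blink
   algorithm is re-implemented);
2. records with both eyes present are averaged, single-eye records pass
   through unchanged;
3. a trial with more than 20% invalid records is rejected. The bound is
   *inclusive*: a trial at exactly 20% is kept, reading "not more than 20%"
   literally;
4. the stimulus-phase series is smoothed with a Savitzky–Golay filter.

Savitzky–Golay parameters are not canonical for pupillometry; the defaults are
`window = 7` samples and `polyorder = 2`, which at the trace lengths involved
is mild smoothing that preserves peak location and amplitude (both are
configurable in `preprocess_config()`). The filter reproduces polynomials up
to the chosen order exactly, which the tests exploit as an oracle. Two open
choices we made and flag rather than assert:

* smoothing is applied to the **stimulus phase only**; the baseline is
  computed from raw (cleaned) prestimulus samples. Smoothing a short baseline
  window mostly re-weights its mean, and the baseline is itself an average, so
  little is at stake either way.
* series shorter than the window (a trial is only guaranteed three stimulus
  measurements) are passed through unsmoothed with a logged warning rather
  than rejected.

## The seven features

With `PS_i` the cleaned stimulus-phase diameters, `t_i` their onset-relative
times and the baseline `BLPS` the mean prestimulus diameter:

| feature | definition | units |
|---|---|---|
| BLPS | mean prestimulus diameter | mm |
| MPDC | `mean(PS) - BLPS` | mm |
| APCPS | `mean((PS - BLPS) / BLPS)` | – |
| PD | `max(PS) - BLPS` | mm |
| E_pupil | Shannon entropy of binned `PS` | bits |
| TTP | time of the (first) maximum | s |
| PDS | `atan` of the OLS slope of `PS` vs `t` from onset through the peak | rad |

Numerical choices:

* **Entropy binning.** Treating pupil size as a discrete variable requires a
  discretization; we bin at a fixed width of 0.01 mm anchored at the trial
  minimum (about the quantization step of typical video eye trackers) and use
  log base 2 so the result is in bits. Both are configurable
  (`feature_config()`); the entropy is therefore a *design choice*, not a
  claim about any particular device's quantization.
* **PDS slope.** The slope is the textbook least-squares estimator
  `m = (Σt·PS − Σt ΣPS / n) / (Σt² − (Σt)² / n)`; the regression window runs
  from stimulus onset through the peak sample inclusive, with time in seconds.
  When the peak falls on the first stimulus sample the slope is undefined and
  the composite extractor reports `PDS = 0` (a flat segment); the low-level
  `compute_pds()` signals an error instead so the degenerate case is never
  silent.
* **Ties.** Peak ties are broken by first occurrence — the conventional
  latency definition.

Two identities are enforced as invariants across every generated trial:
`APCPS × BLPS = MPDC` (algebraic consequence of the definitions, tested to
1e−12 relative tolerance) and `PD ≥ MPDC` (a maximum dominates a mean).

## The synthetic generator

`generator_config()` encodes the study conditions: 24 subjects, 12 trials per
difficulty level each, a 2 s prestimulus phase, digits shown one per second
(3/5/8), and a 2 s retention tail after the last digit. The mean trajectory is
a piecewise-linear ramp from baseline to `baseline + sensitivity × amplitude`,
peaking at the end of digit presentation, followed by exponential decay with a
2 s time constant — the simplest shape with the encoding-ramp/peak/decay
structure reported for serial memory tasks. Defaults:

* baseline ~ Normal(4.0 mm, 0.5 mm) truncated positive, identical across
  difficulty levels by construction (so the baseline feature is null);
* peak amplitudes 0.12 / 0.24 / 0.44 mm for low/medium/high — magnitudes
  anchored to published digit-retention dilations of about a quarter to half
  a millimetre;
* a lognormal, unit-median subject *sensitivity* multiplying the amplitude
  (log-scale spread `amplitude_subject_sd / mean(amplitude)`, default
  0.05 mm / 0.27 mm ≈ 0.19), emulating between-subject response variability;
* Gaussian measurement noise (SD 0.05 mm) plus small independent per-eye
  jitter (SD 0.02 mm);
* blinks as runs of 2–10 consecutive invalid samples, each sample starting a
  run with probability 0.01 — enough to exercise the 20% rule without
  dominating the data;
* device sampling at 50 Hz by default, configurable down to 1 Hz.

What the generator deliberately does **not** emulate: the luminance reflex,
pupil foreshortening with gaze angle, serial correlation of measurement noise,
drift across a session, and any dependence of *baseline* on difficulty.
Passing tests therefore demonstrate that the pipeline recovers the structure
this generator puts in — ordered dilation, null baseline, subject
heterogeneity, blink artifacts — not that it reproduces any particular
laboratory's numbers.

**The null condition.** For type-I-error studies, `null_generator_config()`
equalizes the amplitudes *and* the digit counts across levels. Equal
amplitudes alone would not be a null: with 3/5/8 digits the trials differ in
duration, so duration-linked features (TTP, MPDC through the trajectory
shape) would still separate the labels. The null condition makes the response
distribution label-independent, which is the hypothesis a type-I simulation
must place under the test.

## Statistical analysis

Each feature is modelled as `feature ~ difficulty + (difficulty | subject)`:
difficulty is the fixed effect of interest; subjects contribute random
intercepts and random difficulty effects. Estimation is REML via `lme4`. With
only three levels and two dozen subjects the random-slope covariance is often
singular; the model is then automatically downgraded to a random intercept and
the simplification recorded — a standard, documented simplification rather
than a silent one.

* **Likelihood-ratio test.** The difficulty effect is tested by comparing the
  model with and without the fixed effect, both refit by **ML** — REML
  likelihoods are not comparable across fixed-effect structures — with
  `χ² = 2(ll_full − ll_reduced)` on 2 df.
* **Pairwise contrasts.** "Tukey HSD" has no exact analogue for mixed models;
  we compute the three level differences of the estimated marginal means with
  a multivariate-t family adjustment (`emmeans`), the accepted mixed-model
  counterpart. The three estimates satisfy
  `high−low = (high−medium) + (medium−low)` exactly.
* **Influence screening.** Observations with |standardized conditional
  residual| > 3 (configurable) are flagged and the analysis repeated on the
  retained data ("final" stage). The threshold is a convention; under
  normality it flags ≈ 0.3% of clean observations.
* **Transformations.** No response transformation is applied by default. The
  residuals of simulated features are close to Gaussian by construction; for
  real data with right-skewed features a pre-transformation of the feature
  table is the user's decision, upstream of `run_feature_analysis()`.

## Classification

All `2^7 − 1 = 127` non-empty feature subsets are evaluated for each of seven
classifier families — linear/RBF/sigmoid SVM, a one-vs-rest linear SVC,
LDA, a decision tree, and a 100-tree random forest — 889 evaluations in all,
under stratified 5-fold cross-validation (each configuration trains on 80% of
the rows and tests on the held-out 20%). Design choices:

* **Two "linear SVM" families.** `svm_linear` is the native one-vs-one
  multiclass SVM; `linear_svc` is a one-vs-rest ensemble of binary linear
  SVMs predicting by maximal decision value. These mirror the two distinct
  linear variants common in ML libraries (SVC with a linear kernel vs
  LinearSVC).
* **Hyperparameters** are the families' conventional defaults: cost 1 for all
  SVMs, RBF bandwidth from the median pairwise-distance heuristic on the
  training fold, an unpruned tree (minimum leaf 1), 100 trees for the forest.
  No tuning or nested CV — the wrapper's objective is subset selection, not
  hyperparameter optimisation.
* **Standardization** (training-fold mean/SD) is applied for the margin-based
  families and LDA; trees use raw features.
* **Metrics** come from the *pooled* confusion matrix across folds: per-class
  precision and recall, macro precision/recall as unweighted class means, and
  F1 as their harmonic mean. Two alternatives are emitted alongside — the
  macro average of per-class F1 scores and the fold-averaged macro F1 —
  because published tables rarely state which convention they use.
* **Fold scheme.** By default folds are stratified by difficulty and *not*
  grouped by subject, matching the common protocol for this kind of table;
  `grouping = "subject"` keeps whole subjects out of their own training folds
  and is the leakage-safe option when subject identity may carry label
  information.
* **Ranking ties** are broken towards fewer features, then subset order
  (parsimony first).

## Problem sizes used by the tests

The replicated simulations in the test-suite run the full pipeline at the
default design (24 subjects × 12 trials/level) with a 10 Hz trace grid, and
the type-I study at 24 subjects × 4 trials/level at 5 Hz with 500 replicates.
These rates are analysis-equivalent choices — every stage is
sampling-rate-agnostic and the per-second digit structure is preserved — and
keep the Monte-Carlo studies at hundreds of replicates. The 50 Hz default
remains the generator's device-faithful setting.

## Known limitations

* The generator's trajectory is a stylized ramp/decay; it cannot validate
  pipelines against pupillary light reflexes, gaze-angle artifacts or
  autocorrelated sensor noise.
* The LRT relies on the asymptotic χ² reference; at very small subject counts
  a parametric bootstrap would be preferable.
* The wrapper search's best score is selection-biased upward; the permuted
  label search quantifies that optimism and the subject-grouped fold option
  addresses identity leakage, but honest generalisation estimates for the
  *selected* model require an outer validation split, which is out of scope.
* Blink gaps are removed, not interpolated; features are computed on the
  surviving samples.
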