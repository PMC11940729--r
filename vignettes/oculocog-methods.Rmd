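---
title: "Multimodal oculomotor-cognitive screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal oculomotor-cognitive screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mild cognitive impairment (MCI) is the transitional stage between normal
aging and dementia. Oculomotor control degrades early in that transition:
saccades become slower and less accurate, smooth pursuit lags the target,
spatial working memory weakens. `oculocog` implements a complete desk-scale
counterpart of a multimodal screening pipeline that combines four
eye-movement paradigms (pro/anti-saccades, smooth pursuit, memory-guided
saccades, predictive saccades) with two cognitive test families (Stroop,
forward/backward visuospatial and digit span), summarises each participant
as a canonical 39-value feature vector (31 oculomotor + 8 behavioral), and
classifies participants (MCI vs elderly control vs young) with a
one-dimensional convolutional neural network evaluated under repeated 8:2
holdout.

Because real recordings cannot be shipped with a package, the pipeline is
anchored by a synthetic-cohort generator whose parameters are explicit,
documented phenotype assumptions — not estimates of any real sample. Every
downstream stage (event detection, feature extraction, classification,
evaluation) is validated against that generator's ground truth.

## Task paradigms

Schedules are deterministic under a seed and reproduce the study designs
exactly:

* **Pro/anti-saccades** — 64 formal trials: 4 target positions at ±9.7°
  (horizontal and vertical) × {pro, anti} × 8 repetitions; central fixation
  1.0–1.5 s (uniform); 1 s response window.
* **Smooth pursuit** — 8 trials: {horizontal, vertical} × {0.25, 0.4 Hz}
  × 2; sinusoid of ±10° amplitude. The sine starts at the center moving in
  the positive direction; the design leaves the phase free, and phase 0 is
  the symmetric, convention-free choice. Formal trial length is not
  prescribed either; we use 10 s (the length of a practice trial), which
  covers 2.5 and 4 full cycles at the two frequencies.
* **Memory-guided saccades** — 60 trials: 6 flash locations (±5°, ±10°,
  ±15°) × 10; 100 ms flash; 4.5–5.0 s delay; go signal = fixation offset;
  1 s response window.
* **Predictive saccades** — 25 trials: 5 alternation rates (0.66, 0.8, 1,
  1.33, 2 Hz; inter-step intervals 1.5–0.5 s) × 5; 12 steps between ±10°.
  The first step's direction is randomized per trial since the design does
  not fix it.
* **Stroop** — 90 trials: 3 words × 3 ink colors × 10, randomized; 30
  congruent, 60 incongruent.
* **Span tasks** — adaptive: start at length 3, increment on success,
  repeat on error, stop at 3 consecutive errors or after success at the
  ceiling (9 digits / 8 spatial locations — conventional ceilings, and
  configurable). One point per correct trial. The published description is
  compatible with several trial structures; one-trial-per-length with
  repeat-on-error reproduces the stated termination rule exactly.

Block structure is recorded (it governed rest breaks) but does not affect
analysis. Practice trials are excluded throughout.

## The synthetic cohort generator

Each group (young, elderly control, MCI) is a `GroupProfile` of ~25
parameters: saccade latency moments, anti-saccade error rate, saccade gain
moments, pursuit gain/delay and catch-up rate, memory-guided gain and
failure rate, predictive anticipation probability and latency spread,
fixation noise, blink rate, span abilities, and Stroop accuracy/RT
parameters. The defaults encode the qualitative group structure the
pipeline is meant to detect:

* young adults beat elderly adults by at least one between-subject SD on
  latency, gain, delay and variance-type parameters;
* the MCI profile differs from elderly controls by a **small (~0.2
  between-subject SD) correlated shift** across all oculomotor parameters
  plus a **larger (~0.7 SD) deficit specific to backward digit span**.

The MCI oculomotor effect is deliberately weak per feature and shared
across tasks through a latent severity factor (individual parameters
correlate at ρ ≈ 0.5). This is the configuration in which no single eye
feature separates MCI from controls reliably but a multivariate classifier
can accumulate the correlated evidence — the regime the multimodal design
targets. Between-subject jitter uses a 10% coefficient of variation, which
produces heavily overlapping group distributions.

Traces are 60 Hz monocular gaze. Saccades are minimum-jerk displacements
with a main-sequence duration rule (≈ 20 ms + 2 ms/deg); pursuit is the
target delayed by `pursuit_delay` and scaled by `pursuit_gain`, plus
catch-up saccades at a Poisson rate that close the accumulated positional
error; blinks are invalid gaps of 0.1–0.2 s; fixation noise is white with
group-specific SD (0.12–0.19°). White noise at 60 Hz is spectrally much
harsher than real tracker noise of the same amplitude, so these SDs are
chosen to give realistic *velocity* noise under the package's smoothing;
the generator does not attempt to match a real tracker's noise spectrum,
pupil dynamics, or microsaccades. Consequently, passing tests demonstrate
correctness of the pipeline's logic and its behaviour under the stated
phenotype model — not performance on real recordings.

## Event detection and features

Preprocessing interpolates invalid gaps ≤ 75 ms, excludes longer gaps,
flags trials with < 50% valid samples as unusable, and smooths positions
with a Savitzky–Golay filter (window 5 samples, order 2; larger windows
distort 40 ms saccades at 60 Hz). Saccades are maximal runs of 2-D speed
above 30°/s lasting ≥ 2 samples — thresholds appropriate for 60 Hz data,
where finer distinctions are unresolvable. Two numerical details matter at
this sampling rate:

* the **onset** is the first above-threshold sample. Central differences
  anticipate a movement by one sample, and the smoother by up to two, so
  refining onsets backward to a local speed minimum would antedate them by
  ~2 samples; with the chosen rule the mean latency bias is ≈ −5 ms,
  within one sample.
* the **displacement** (amplitude, direction, landing) is measured between
  short settling windows flanking the event rather than at the endpoint
  samples themselves, which still carry smoothing transients. This keeps
  noiseless gain recovery within 0.005 and amplitude recovery within
  0.04° at 9.7°.

The 31 eye features follow the canonical task blocks: pro/anti (fixation
dispersion, accuracies, latencies, gains — gain is the landing displacement
projected on the instructed axis over 9.7°, so oblique errors do not
inflate it), pursuit (fixation dispersion, saccade compensation, error
variances and delays per axis × frequency), memory-guided (dispersion,
gains at 5/10/15°), predictive (dispersion, latency variance, mean latency,
mean gain). Definitions the source design leaves open were fixed as
follows, once:

* pursuit **delay** is the lag in [0, 0.5] s on the 1-sample grid
  maximizing the cross-correlation between the de-saccaded gaze and the
  target along the motion axis; **variance** is the variance of the
  positional error after shifting the target by that delay (deg²);
* **saccade compensation** is the summed catch-up amplitude along the
  motion axis divided by the total target path length (dimensionless);
  count-rate or mean-amplitude alternatives were considered and not used;
* predictive **variance** is the variance of step latencies (s²); steps
  2–12 are scored (step 1 is unpredictable), a step's saccade must move in
  the step's direction within [−0.25, +0.5] s around it, and gain is
  normalized by the full 20° step;
* **fixation dispersion** is the RMS distance of samples from their
  centroid — translation- and rotation-invariant.

Missing features (e.g., a condition with no usable trials) are imputed with
training-fold medians inside the evaluation loop; participants missing an
entire task block are dropped, mirroring whole-participant exclusion.

## The classifier

The CNN is implemented from first principles (no deep-learning runtime is
used): conv1d(1→16, kernel 2, stride 1, same-length) → ReLU → maxpool(2) →
conv1d(16→32) → ReLU → maxpool(2) → flatten → FC(4096) → ReLU → dropout →
FC(256) → ReLU → dropout → FC(n_classes), softmax cross-entropy, Adam
(lr 0.001, β₁ 0.9, β₂ 0.999) with the learning rate multiplied by 0.9
every 10 epochs. With 39 inputs the sequence lengths run 39 → 19 → 9, so
the flattened width is 32 × 9 = 288. Same-length padding with an even
kernel requires one asymmetric pad position, placed at the sequence end.
"Reducing the learning rate by 10%" is read literally as ×0.9 (not
set-to-10%). Pooling size/stride 2 is the only conventional choice that
meaningfully reduces computation at length 39. Dropout 0.5 after FC1 and
FC2, 100 epochs and batch size 16 are package defaults (these
hyperparameters are not prescribed). Correctness of the backpropagation is
enforced by a finite-difference gradient check in the test suite; the Adam
update runs through a small compiled kernel because the fused in-place
update avoids allocating ~10 full-tensor temporaries per step.

Because convolution couples *adjacent* features, the feature order inside
the vector is part of the model definition; it is fixed package-wide and
documented in `EYE_FEATURE_NAMES` / `BEHAVIOR_FEATURE_NAMES`.

The FCNN ablation uses the identical FC stack without conv/pool; SVM
(radial kernel, probability estimates) and random forest baselines use
their standard library implementations at defaults, seeded.

## Evaluation protocol

`repeated_holdout()` runs 10 independent 8:2 splits. Splits are stratified
by group by default — with 40 MCI among 128, unstratified 20% folds can
lose a class; a flag restores unstratified splitting. Per repeat the
normalizer (median imputation + z-score) is fitted on the training fold
only. Reported: per-repeat accuracies, mean (SD) accuracy, per-class hit
rates (recall), confusion counts, misclassified IDs, and for binary tasks
the ROC AUC of the MCI probability — pooled across the 10 test folds as the
headline number, with the per-repeat average also available (pooling is a
choice; both are surfaced). The ablation suite covers the seven canonical
feature sets (combined, eye-only, behavior-only, combined minus each task);
the model comparison covers cnn/fcnn/svm/rf. The young-vs-elderly Welch
screen reports raw p-values by default (a Benjamini–Hochberg option
exists but is off, matching the descriptive use of the screen), and
chance-level bands come from label permutation rather than a fixed 1/k so
class imbalance is respected.

## Problem sizes and determinism

Test-suite cohorts are 22–48 participants and protocol tests use a
narrower FC stack (32, 16); the acceptance script simulates the full
31/57/40 cohort and trains the full-width network for 50 epochs per
repeat, a size at which training losses have plateaued on these data while
a complete run stays comfortable on a single CPU. All randomness — trial
schedules, cohort draws, splits, initialization, shuffling, dropout —
derives from user-supplied seeds; identical seeds give bit-identical
results on the same platform.

## Known limitations

* The generator's group effects are assumptions; published effect sizes
  for the eye features are distributional figures only, so classification
  accuracies obtained here characterize the synthetic phenotype model, not
  the real cohorts.
* Only monocular 60 Hz data are modelled; binocular measures,
  microsaccades, pupil size and MCI subtypes are out of scope.
* The velocity-threshold detector is not adaptive; at much higher noise
  levels than the defaults its false-alarm behaviour would need re-tuning.
* Span-task trial structure beyond the stated termination rule
  (attempts per length, length decrements) is one of several defensible
  readings.
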