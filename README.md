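# oculocog

Multimodal oculomotor and cognitive assessment for mild cognitive
impairment (MCI) screening, as a reusable, tested R pipeline.

MCI is the transitional stage between normal aging and dementia, and
oculomotor control degrades early in that transition. `oculocog`
implements a complete screening analysis that combines **four eye-movement
paradigms** — pro/anti-saccades, smooth pursuit, memory-guided saccades,
predictive saccades — with **two cognitive test families** — Stroop and
forward/backward visuospatial/digit span. Each participant is summarised
as a canonical 39-value feature vector (31 eye-movement + 8 behavioral
features) and classified (MCI vs elderly control vs young) with a
one-dimensional convolutional neural network under a repeated-holdout
protocol, alongside FCNN, SVM and random-forest baselines.

The package is intended for methods researchers in eye-tracking-based
cognitive screening: it provides the full chain from raw 60 Hz gaze traces
to published-style result tables, with every stage validated against a
synthetic-cohort generator whose phenotype parameters are explicit and
configurable.

## What is computed

For gaze position `g(t)` and target `f(t)` (degrees of visual angle):

* **Saccade detection**: maximal runs of 2-D speed `|g'(t)| > 30°/s`
  lasting ≥ 2 samples at 60 Hz, after Savitzky–Golay smoothing (window 5,
  order 2) and blink-gap handling.
* **Saccade latency** `= t_onset − t_target`; **gain** `= projection of
  the landing displacement on the instructed axis / eccentricity`.
* **Pursuit delay** `δ̂ = argmax_δ corr(g(t), f(t − δ))` on a 1-sample lag
  grid in [0, 0.5] s; **variance** `= Var[g(t) − f(t − δ̂)]` (deg²);
  **saccade compensation** `= Σ catch-up amplitudes / target path length`.
* **Predictive latency**: signed latency of the saccade crossing with each
  target step (negative = anticipatory); its variance across steps (s²).
* **Span scoring**: adaptive runs starting at length 3, terminated at 3
  consecutive errors, one point per correct trial; **Stroop** accuracy and
  mean correct-trial RT per congruency.
* **Classifier**: conv1d(1→16, k2) → pool → conv1d(16→32, k2) → pool →
  FC(4096) → FC(256) → FC(classes), ReLU, dropout, softmax cross-entropy,
  Adam (lr 0.001) with ×0.9 step decay every 10 epochs — implemented from
  first principles with a finite-difference-verified backprop.
* **Evaluation**: 10 stratified 8:2 splits; mean (SD) accuracy, per-class
  hit rates, confusion counts, misclassified IDs, pooled ROC AUC; ablation
  over 7 feature sets; model comparison over 4 classifiers.

## Worked example

```r
library(oculocog)

# a small labeled synthetic cohort: 60 Hz gaze + behavioral responses
cohort <- generate_cohort(n_young = 4, n_control = 6, n_mci = 6, seed = 42)

# the canonical 39-feature table
features <- build_feature_table(cohort)
features[1:3, c("participant_id", "group", "pa_mean_latency",
                "sp_mean_delay", "span_bwd_digit")]
#>   participant_id group pa_mean_latency sp_mean_delay span_bwd_digit
#> 1      young_001 young       0.1896243    0.07291667              4
#> 2      young_002 young       0.2156867    0.10000000              4
#> 3      young_003 young       0.1719760    0.08333333              7

# repeated 8:2 holdout, combined features (random forest for speed here;
# model_kind = "cnn" runs the convolutional network)
res <- repeated_holdout(features, subset = "combined", model_kind = "rf",
                        config = model_config(seed = 1),
                        scheme = split_scheme(n_repeats = 10, base_seed = 7))
res
#> <oc_eval_result> rf: accuracy 70.00% (24.60) over 10 repeats
#>   hit rates: control 50.00% (52.70), mci 60.00% (51.64), young 100.00% (0.00)

# young-vs-elderly feature screen (Welch t-tests)
screen <- group_difference_screen(features)
screen[screen$feature == "pa_mean_latency",
       c("feature", "t_young_elderly", "p_young_elderly")]
#>           feature t_young_elderly p_young_elderly
#> 5 pa_mean_latency       -7.437093    6.745856e-05
```

The first line reads: mean pro/anti-saccade latency ~0.19 s for a young
participant, pursuit delay ~0.07 s, backward digit span 4 points. The
evaluation result reports the mean (SD) test-fold accuracy over the 10
splits and the per-class hit rates (recall); young participants are
perfectly separable from the elderly groups even at this toy cohort size,
while control-vs-MCI discrimination is the genuinely hard part of the
problem. The screen confirms young adults are significantly faster.

Larger entry points: `ablation_suite()` (the seven feature-set rows),
`model_comparison()` (cnn/fcnn/svm/rf), `feature_behavior_correlations()`,
`write_cohort_csv()` / `read_cohort_csv()` (gaze-CSV dialect for external
recordings), and the command-line front end `inst/scripts/oculocog`.

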