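# ecgorigin

Machine-learning localization of idiopathic ventricular arrhythmia (IVA)
origins from single-beat 12-lead ECGs.

When a premature ventricular complex (PVC) or ventricular tachycardia (VT)
is treated by radiofrequency catheter ablation, the operator must find the
myocardial site firing the arrhythmia. The site leaves a signature in the
QRS morphology of the 12-lead surface ECG, so a classifier trained on beats
labeled by their confirmed successful-ablation site can predict the origin
*before* mapping, shortening the procedure and reducing complication risk.
`ecgorigin` implements that pipeline end to end for electrophysiologists and
ML researchers working with beat-level ECG data:

- **Signal preparation** — coiflet-5 wavelet decomposition with per-level
  SURE (Stein's Unbiased Risk Estimate) soft thresholding for denoising;
  beat windows of `W` samples anchored on the lead-II R-wave peak
  (`pre = ⌊W/2⌋` samples before the reference line, the reference sample
  counted as the first point after it), flattened to a `12 × W` feature
  vector per recording.
- **Anatomical label schemes** — the four-level hierarchy of 21 leaf sites
  (LCC, RCC, AMC, …, RAPM, epicardium of the LV summit) with collapse maps
  onto 3 regions, 5 outflow/non-outflow tracts, and 18 groups, plus a
  partial-credit matrix for *adjusted accuracy* that rewards clinically
  interchangeable confusions (default: weight 0.5 between sites sharing a
  parent, overridable from CSV).
- **Cohorts** — patient-disjoint stratified 80/10/10 train/validation/test
  splitting (545 patients ⇒ 436/55/54), and majority-matching oversampling
  of training minorities (e.g. a 25-recording class duplicated up to the
  1,694-recording majority).
- **Window search** — exhaustive grid over window sizes (200–1,000 samples,
  step 10, at 2,000 Hz) scored by a fixed random forest on validation
  accuracy.
- **Model zoo** — a data-driven registry of 21 runnable classifier families
  (6 tree ensembles, 15 base learners), each alone or under one-vs-rest /
  one-vs-one / error-correcting-output-codes wrappers, tuned by
  validation-F1 grid search; extremely randomized trees is the reference
  winner.
- **Evaluation** — one-vs-rest SE/SP/PPV/NPV/F1/balanced accuracy per class
  with support-weighted averages, percentile bootstrap 95% CIs (2,000
  replications), adjusted accuracy, and rank-of-true-site (top-k) failure
  analysis.
- **Interpretation** — impurity-based feature-importance heat maps over
  (lead, offset) cells and Gaussian-kernel-smoothed average beat
  morphologies per class.
- **Synthetic generator** — a seeded class-conditional 12-lead beat
  simulator (Gaussian QRS lobes, patient-shared jitter, white noise,
  configurable class imbalance) so the whole pipeline is exercisable and
  testable without clinical recordings.

## Worked example

```r
library(ecgorigin)

# a seeded synthetic cohort: 10 classes, 50:1 imbalance, 2,000 Hz beats
ds <- simulate_dataset(default_benchmark())
nrow(ds)                                   # 501 recordings, 63 patients

cfg <- experiment_config(scheme_id = NULL, window = 160,
                         base_seed = 11, bootstrap_B = 500)
res <- run_experiment(cfg, ds)
res
#> <ecg_experiment> scheme as-is | window 160 | winner extremely_randomized_trees | test accuracy 0.9683

glance(res)[, c("accuracy", "F1", "accuracy_ci_lower", "accuracy_ci_upper")]
#> # A tibble: 1 × 4
#>   accuracy    F1 accuracy_ci_lower accuracy_ci_upper
#>      <dbl> <dbl>             <dbl>             <dbl>
#> 1    0.968 0.985             0.921             1
```

The run splits patients 80/10/10, oversamples the training minorities,
builds 160-sample beat windows (1,920 features), fits extremely randomized
trees, and blind-tests on held-out patients: 96.8% of test beats are
assigned to the correct synthetic class, with a bootstrap 95% CI of
(0.92, 1.00). `autoplot(res$report$confusion)` draws the confusion matrix;
`top_features(importance_map(res$model))` lists the most informative
(lead, offset) cells in "nth point after the reference line" terms.

With clinical data, point `load_dataset()` at a manifest of per-beat CSVs
(`#`-prefixed metadata, one column per lead), pick a scheme 1–4, and use
`window = "search"` or the per-scheme defaults `scheme_default_windows()`
(250/550/360/320 samples). A thin CLI with the same verbs lives in
`inst/exec/ecgorigin`.

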