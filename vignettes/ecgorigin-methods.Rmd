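---
title: "Methods: beat-level ECG classification of ventricular arrhythmia origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat-level ECG classification of ventricular arrhythmia origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgorigin)
```

## The problem and the model

Idiopathic ventricular arrhythmias (PVC/VT in structurally normal hearts)
are cured by ablating the myocardial site that fires them. Because the
activation wavefront spreads from that site, its location shapes the QRS
complex seen on the 12-lead surface ECG. `ecgorigin` treats origin
localization as supervised multiclass classification: the unit of analysis
is a single beat — a `12 × T` voltage matrix sampled at 2,000 Hz — labeled
by the site whose ablation abolished the arrhythmia, and the feature vector
is simply the denoised voltages in a window around the lead-II R-wave peak.
No hand-crafted indices (transition zones, amplitude ratios) are extracted:
tree ensembles operate on the raw windowed samples, which also makes the
fitted model interpretable cell-by-cell through impurity importances.

Four nested label schemes serve different clinical questions: 3 general
regions (LV endocardium, RV endocardium, epicardium of the LV summit),
5 tracts (outflow / non-outflow per ventricle plus the epicardial summit),
18 anatomical groups, and 21 exact sites. A single leaf-labeled dataset
serves all four through deterministic collapse maps; the maps compose, so a
scheme-4 label determines every coarser label.

## Preprocessing

**Denoising.** Each lead is independently decomposed with the orthonormal
coiflet-5 wavelet (periodized transform; odd-length scales extended by
repeating the last sample). Detail coefficients at every level are
soft-thresholded at the SURE-minimizing threshold for that level, with the
noise scale estimated once from the finest detail level by the median
absolute deviation; approximation coefficients are untouched. Soft
thresholding is the standard companion of the SURE criterion. The
decomposition depth defaults to the maximum the series length supports,
capped at 8. Series shorter than the 30-tap filter support are returned
unchanged with a warning. Whether to denoise before or after window
extraction is not dictated by the data model; the package denoises the full
recording first, so the window never sees filter edge effects.

**Reference line and windows.** The anchor is the lead-II R-wave peak: the
annotated index when present, otherwise the maximum of |lead II| (each
recording contains one QRS complex, so the global extremum is the R peak;
ties resolve to the first sample). A window of `W` samples takes
`pre = ⌊W/2⌋` samples before the anchor and `W − pre` at-and-after it — the
reference sample is "the first point" of the post side, so feature offsets
run `−pre..−1, 1..post` with no offset 0. Windows overrunning a record
boundary are edge-padded rather than rejected, so the window search can
probe sizes up to 1,000 samples on beats near boundaries. Features are the
12 lead windows concatenated in fixed lead order (I, II, III, aVR, aVL,
aVF, V1–V6), named `LEAD_OFFSET`.

**Window search.** Candidate sizes run 200–1,000 samples in steps of 10
(100–500 ms at 2,000 Hz). Each candidate is scored by a 100-tree random
forest (fixed seed, default hyperparameters) trained on the training
cohort and scored on validation accuracy; the argmax wins, ties going to
the smallest window since narrower windows are cheaper. The evaluator's
hyperparameters are deliberately fixed — the search ranks windows, not
forests. Single-pass validation accuracy is used; a `repeats` argument
averages over evaluator seeds when the curve is noisy. The per-scheme
optima shipped in `scheme_default_windows()` (250/550/360/320 samples) are
outcomes on the original clinical data and are provided as defaults, never
asserted by tests.

## Cohorts

Splitting is by **patient**, stratified by leaf-level class, so recordings
of one patient never straddle cohorts (the generalization claim is about
new patients, not new beats — the synthetic generator's patient-shared
jitter makes this distinction measurable). Within each class the patients
are shuffled by seed and assigned by quota: floor shares per cohort, extras
by largest fractional remainder with ties broken train > validation > test,
then a coverage step guaranteeing at least one validation and one test
patient for any class with three or more patients (pulled from training).
This rule reproduces both published anchor points — 545 patients split
436/55/54, and a five-patient class splits 3/1/1. A single-patient class
goes to training with a warning. Recording shares that drift more than two
percentage points from 80/10/10 within a class are warned about, not
repaired: patient-level assignment constrains recording-level exactness.

Training imbalance is addressed by plain duplication oversampling: each
class is resampled with replacement until it matches the majority class's
training count. Validation and test cohorts are never oversampled. No
jitter/SMOTE-style synthesis is added — duplication keeps the training
distribution honest for tree learners and is trivially reproducible.

## The model zoo

The registry enumerates 21 runnable families — six ensembles (bagged trees,
random forest, AdaBoost/SAMME, gradient-boosted trees, extreme gradient
boosting, extremely randomized trees) and fifteen base learners (CART,
k-NN, nearest centroid, Gaussian/multinomial/complement/Bernoulli naive
Bayes, LDA, QDA, multinomial logistic regression, MLP, ridge, linear SGD,
passive-aggressive, linear SVM) — standalone and under one-vs-rest,
one-vs-one, and error-correcting-output-codes wrappers, plus two inert
deep-learning stubs (residual CNN, LSTM with attention) that are listed but
flagged not runnable. The registry is plain data (JSON round-trippable);
hyperparameter grids ship small and editable because no canonical grids
exist. Where an established R package implements a family it is the
backend (ranger, xgboost, rpart, e1071, MASS, glmnet, nnet); families
without an R backend (the discrete naive Bayes variants, nearest centroid,
k-NN probabilities, SAMME, linear SGD, passive-aggressive, the three
wrappers) are implemented in-package as their textbook algorithms.

Hyperparameters are chosen by exhaustive grid evaluation on the validation
cohort, scored by support-weighted F1 in which a class with undefined F1
(never predicted) contributes 0 — renormalizing over defined classes
instead would let a degenerate model that ignores minority classes win the
comparison. Ties go to the first-listed combination. The historical
protocol of *selecting* the final model family by test-cohort accuracy is
reproduced under `select_on = "test"` with a printed leakage caveat;
`select_on = "validation"` (the default in `experiment_config()`) is the
leak-free variant. Recording-id fingerprints make train/validation overlap
a hard error.

## Evaluation

Per-class metrics come from the one-vs-rest reduction of the confusion
matrix: SE, SP, PPV, NPV, F1, and balanced accuracy. Any 0/0 ratio is
reported as `NA` — undefined, distinct from zero — and weighted averages
renormalize over defined classes (selection scoring, above, is the one
deliberate exception). Adjusted accuracy generalizes accuracy through a
unit-diagonal credit matrix: `Σ counts[i,j]·weights[i,j] / n`. The
published partial-credit assignments are not available, so the default
matrix awards 0.5 to sibling sites under the same hierarchy parent and 0
elsewhere; it reduces exactly to plain accuracy at weight 0, and any
externally supplied matrix can be dropped in via CSV. Confidence intervals
are percentile bootstrap over recordings (2,000 replications, two-sided
95%); the percentile method is the minimal faithful reading of
"bootstrapping", and BCa is deliberately out of scope. A metric undefined
on more than 10% of replicates yields an undefined CI with a diagnostic
rather than a silently biased one. Failure analysis tabulates the rank of
the true site in the probability-ordered prediction list (top-k, default
k = 3).

## The synthetic generator

`simulate_dataset()` produces beats as a deterministic base QRS (three
Gaussian lobes per lead; lead II carries the dominant R lobe, amplitude 1,
at the planted peak) plus a class-specific smooth perturbation supported
only on configurable *discriminative offsets* and scaled linearly by
`separation`, plus a patient-shared smooth jitter, plus white noise. It
emulates exactly the properties the pipeline exercises: class-conditional
morphology, within-patient correlation, truthful R-peak annotation, class
imbalance, 2,000 Hz sampling. It does **not** emulate cardiac
electrophysiology — no torso projection, no re-entry dynamics, no realistic
lead fields — so green tests certify pipeline mechanics and statistical
contracts, not clinical performance.

Defaults were fixed once as plausible desk-scale conditions: `separation
1` (between-class template distance comparable to the QRS amplitude scale),
`noise_sd 0.05` and `patient_jitter_sd 0.05` (5% of R-peak amplitude),
records of 2,400 samples (1.2 s) with the beat at midpoint. The frozen
benchmark (`default_benchmark()`) uses 10 classes with counts
150:100:80:60:40:30:20:12:6:3 — a 50:1 majority:minority ratio echoing the
shape, though not the absolute 150:1 extreme, of the clinical per-site
distribution, capped so a full end-to-end run stays in tens of seconds —
and 3–10 patients per class so every class survives patient-level
splitting. On this benchmark a 160-sample window (the discriminative
offsets span ±60) with extremely randomized trees reaches ≥ 0.95 test
accuracy, and the same pipeline at `separation 0` on a balanced roster
falls to the 1/k chance floor.

## Numerical choices and degenerate inputs

- Probability ties in rankings break by class-code order; argmax ties in
  window search break toward the smaller window; grid-search ties break
  toward the first-listed combination. All are deterministic.
- Wrapper probabilities: one-vs-rest normalizes the per-class positive
  probabilities (uniform if all zero); one-vs-one averages pairwise
  probabilities as votes; ECOC decodes by L1 distance to the codeword
  through a softmax. These are rankings-preserving conventions, not
  calibrated probabilities.
- Constant or all-zero leads are fixed points of the denoiser (their detail
  coefficients vanish); a zero-noise estimate skips thresholding.
- Empty datasets yield 0-row feature matrices with full column naming;
  empty confusion matrices are valid but accuracy on them is an error.
- Seeds are explicit everywhere (`withr::with_seed`); no function mutates
  the global RNG state.

## Problem sizes used by the test suite

The suite runs simulations small enough to keep the whole run under a few
minutes on one core: 3-class datasets of 27–54 recordings for mechanics,
20-seed loops for the splitting/oversampling and window-recovery
properties (3 × 18 recordings, candidate windows {60, 100, 140, 180},
signal planted at offsets ±55–60 so sub-threshold windows see pure noise),
and 4 full benchmark runs (501 recordings, 1,920 features) for the
end-to-end accuracy and chance-floor checks. Bootstrap contracts are
checked at n = 1,000, B = 2,000 against the binomial closed form.

## Known limitations

- The partial-credit matrix is a documented stand-in; adjusted accuracies
  computed with it are not comparable to published adjusted accuracies
  until the published matrix is supplied.
- The registry's enumeration (86 combinations) is configuration-driven;
  the historical count of 98 tuned combinations is not reconstructible
  from public information and is neither reproduced nor asserted.
- Deep-learning comparators exist only as inert registry stubs.
- WFDB input, Holter-length segmentation, and interval measurements
  (QT/PR) are out of scope; the loader expects single-beat records.
- Clinical headline numbers (98%+ accuracy on 21 sites) require the
  original clinical dataset and cluster-scale search; nothing in this
  package's tests claims them.
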