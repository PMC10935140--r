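---
title: "The fall-detection chain: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fall-detection chain: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fallarc` implements a complete Activity Recognition Chain for wrist-worn
fall detection: a synthetic multi-source IMU corpus generator,
harmonization of heterogeneous sources, sliding-window featurization,
two-stage random-forest feature selection, cost-sensitive SVM and neural
network classifiers with a magnitude-threshold baseline, and
subject-disjoint evaluation. This vignette explains the science of each
stage, the parameters that matter, and the choices we made where more than
one defensible design existed.

## The problem

A fall detector watching a wrist IMU must answer, every couple of seconds:
does this window contain a fall? Three properties make this hard in
practice. First, public simulated-fall corpora are *heterogeneous* —
sampling rates of 18, 20 or 50 Hz, acceleration in g or m/s², angular
velocity in rad/s or deg/s. Second, the problem is *imbalanced*: falls are
roughly 2–10% of windows per source, so a classifier that never fires
looks 95% accurate. Third, repeated trials by the same subject make naive
cross-validation *leak*: a model that memorizes a person's movement style
scores well on that person's held-out trials while generalizing poorly.
The chain addresses the three issues with unit/rate harmonization,
inverse-class-frequency cost weighting, and grouped (subject-disjoint)
folds respectively.

## The synthetic corpus: what it emulates, and what it does not

The generator (`generate_trial()`, `generate_dataset()`) emulates the
*structure* of multi-source wrist recordings, not their biomechanics. Each
trial is 15 s (the monitoring span typical of simulated-fall protocols).
ADL trials are gravity (≈1 g DC, slightly tilted per trial) plus a
quasi-periodic movement component with per-activity frequency and
amplitude, plus Gaussian sensor noise. Fall trials are piecewise: a
pre-fall movement segment; a half-sine impact spike on the acceleration
norm along a random direction, reaching `impact_peak` (the sample nearest
the spike center is pinned at the peak, and sensor noise is attenuated
inside the impact so the configured peak is the realized one); and a
quiescent lying segment whose gravity axis is rotated by
`post_impact_orientation_change`. Gyroscope channels mirror this with a
spike to `gyro_peak` at impact.

Per-sample labels are emitted directly by the generator: the fall label
spans the impact and, by default, the entire lying segment
(`label_post_impact_s = Inf`). An earlier design labeled only the first
seconds of lying, but that creates label aliasing — lying windows beyond
the cutoff are feature-identical to fall-labeled lying windows yet carry
label 0 — an artifact no manual labeling protocol produces. With the
impact placed uniformly at 0.65–0.80 of the trial, the windowed fall
prevalence of the default corpus lands around 7%, inside the 2–10% band
real wrist corpora show.

The default study configuration (`default_generator_config()`) mirrors the
heterogeneity the harmonizer must handle: three sources at (18 Hz, g,
rad/s), (20 Hz, m/s², deg/s) and (50 Hz, g, rad/s), each with 10 subjects
performing 5 ADL and 2 fall activities 3 times. One ADL class deliberately
produces clapping spikes above 2.5 g with little rotation, so
magnitude-threshold detection faces realistic false positives while the
learned models can use gyroscope and orientation cues.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: soft-tissue and sensor transfer functions,
near-fall events, age-dependent kinematics, label noise from human
annotators, and the sheer diversity of real ADL. Synthetic falls are far
more stereotyped than real ones; the end-to-end metrics here are
mechanism checks (the chain can recover a known planted signal under
realistic imbalance and heterogeneity), not performance claims for
deployment.

## Harmonization

Units are unified to g (÷ 9.80665 from m/s²) and rad/s (× π/180 from
deg/s). Resampling to the 18 Hz corpus rate is linear interpolation onto a
uniform grid spanning the original time range — the output has
`floor(span × rate) + 1` samples, so duration is preserved to within one
target sample period, and affine signals are reproduced exactly. We apply
no anti-alias filter by default because subsampling here is a rate
alignment step, not a spectral analysis; an optional moving-average
`lowpass` flag exists for users who want it. Labels are categorical, so
they transfer from the *nearest* original sample rather than being
interpolated.

Files containing any non-finite value are removed whole (not row-wise),
including when the offending value sits in the label column — a file whose
labels cannot be trusted is no better than one whose sensors cannot.

Min-max normalization maps each channel affinely to [−1, 1]. Two fitting
scopes are provided because the methodologically interesting question —
fit before or after the train/test split — has no universally right
answer: `per_dataset` fits over all of a dataset's recordings (the common
practice when datasets are normalized once during preparation; it leaks
test extremes into training, which matters little for min/max but is a
leak nonetheless), while `fit_on_train` fits on the training partition
only and applies those parameters elsewhere, the leakage-free variant used
naturally by the cross-dataset driver. Constant channels map to 0 (the
midpoint) to avoid dividing by zero. Normalizing an already-normalized
corpus with refitted parameters is a no-op to machine precision.

## Windows and features

Windows are 2 s with 50% overlap: at 18 Hz, `window_len = 36` samples and
`stride = 18`, so a 15 s trial yields exactly
`floor((270 − 36)/18) + 1 = 14` windows; trailing partial windows are
discarded. Each window's label is the mode of its per-sample labels, with
exact ties resolved to *fall* — in a detector, the asymmetric cost of a
miss argues for sensitivity at the margin.

The 13 per-channel statistics have fixed, oracle-tested definitions:

- `zero_crossings`: strict sign changes of the raw signal
  (`x_i · x_{i+1} < 0`); zeros do not count, and the signal is not
  mean-centered first (on accelerometer data the DC gravity component is
  informative, and centering would erase the distinction between
  oscillation about zero and about 1 g).
- `std`: population (1/n) standard deviation; `skewness` = m₃/m₂^{3/2}
  and `kurtosis` = m₄/m₂² (non-excess), both defined as 0 when m₂ = 0.
- `q1`, `median`, `q3`: linear-interpolation quantiles.
- `energy`: mean of squared values — mean signal power, a time-domain
  quantity equal (by Parseval, up to normalization) to the mean spectral
  energy, so `rms² = energy` holds as an internal consistency identity.
- `autocorr`: the lag-1 sample autocorrelation coefficient, 0 for
  zero-variance windows. Lag 1 is the smallest lag that distinguishes
  oscillatory from noisy windows at 18 Hz; higher lags are left to the
  user.

Six channels × 13 statistics give the 78-column feature matrix, in a
documented fixed order (`fd_feature_columns()`). Each row also carries
`peak_acc_norm_g`, the window's maximum acceleration norm computed from
*raw* (pre-normalization) g, which is what the threshold baseline
consumes.

## Feature selection

Stage 1 trains a 200-tree random forest and ranks features by normalized
mean-decrease-in-impurity (Gini) importance; importance ties are broken
lexicographically so the ranking is reproducible. Stage 2 takes the
features with above-mean importance and measures, for each, the change in
subject-disjoint CV accuracy when that single feature is excluded;
features whose exclusion costs accuracy (delta > 0) are kept, in ranking
order. Both keep rules are configurable (`top_k=K`, `all`), because no
single threshold suits every corpus.

Two honest caveats, both visible on the synthetic corpus. First,
one-at-a-time exclusion underestimates *grouped* redundancy: when several
features carry the same signal, removing any one of them costs nothing,
so on a highly separable, redundant corpus the positive-delta rule can
keep very few features — occasionally none, in which case the top-ranked
feature is retained with a warning. This is a property of the screening
method, not a bug; wrapper searches that handle feature interactions are
out of scope. Second, forest feature subsampling means the exact
importance values depend on column order through which features compete
within a tree; the ranking is deterministic for a fixed input, and signal
features are stable under reordering, but the noise tail near the
threshold can differ.

The ablation probe uses 101 trees — an odd count, so binary majority
votes cannot tie — and seeds both training and prediction; random
tie-breaking at prediction time would otherwise make the deltas
irreproducible. Plain accuracy is the default screening metric (the
conventional choice for this style of screening), with balanced accuracy
available for heavily imbalanced candidate sets.

## Cost-sensitive models

Class weights are the inverse class frequency, `w_c = n/(2 n_c)`,
normalized so a balanced corpus gives both classes weight 1; the weight
ratio equals the inverse count ratio exactly, and the minority (fall)
class always gets the larger weight. A literal frequency-proportional
variant (`w_c = n_c/n`, which up-weights the *majority* class) is
available behind `literal = TRUE` purely for comparison — giving more
weight to the rare class is the entire point of cost-sensitive fall
detection.

**SVM.** The soft-margin objective scales each sample's slack penalty by
its class weight, i.e. the effective cost is `C · w_{y(i)}`. This is
delegated to libsvm (via `e1071`) per-class weighted costs; the
decision-value sign is reoriented at fit time so positive margins always
mean *fall*. The kernel defaults to RBF with `gamma = 1/(p · var(X))`
(the scale-aware choice; `linear` available), `C = 1`. Inputs are
z-scored inside the model (parameters stored and reapplied at prediction)
so heterogeneous feature scales do not distort the kernel. Doubling all
class weights while halving C leaves the solution unchanged — a useful
identity test of the weighting path.

**ANN.** A single hidden layer of tanh units (default 32) with a sigmoid
output, trained by full-batch gradient descent (momentum 0.9, learning
rate 0.5, 400 epochs) on the class-weighted mean squared error
J = 1/(2n) Σ wᵢ(ŷᵢ − yᵢ)². Sample weights are rescaled to mean 1 — the
absolute scale is absorbed by the learning rate; only the ratio matters.
We chose a fixed epoch budget over early stopping on a validation split:
a held-out split would consume training subjects, inject another source
of randomness into an already stochastic pipeline, and break the clean
property that training loss is monotonically non-increasing under a small
learning rate (a test we keep as an optimization sanity check, run with
momentum 0). Initialization is seeded uniform; the trainer is
deterministic given (data, hyperparameters, seed). Inputs are z-scored
internally like the SVM's.

**Threshold baseline.** A window is a fall iff its peak acceleration norm
reaches 2.5 g. It has no trainable state; its continuous score for
ROC/maxSeSp purposes is the peak norm itself. On the synthetic corpus it
fails in both directions by construction — lying-after-impact windows
carry the fall label but no spike, and clap windows spike without
falling — which is precisely the argument for learned detectors.

## Evaluation

Folds are built over subjects, not windows: distinct `(dataset, subject)`
keys are sorted (locale-independently), shuffled with the seed, and dealt
round-robin into k = 10 folds, so fold sizes differ by at most one
subject and the assignment depends only on the subject set, never on row
order. If some fold's test windows are single-class, the shuffle is
retried up to 20 times. When a dataset has fewer subjects than k, k is
reduced with a warning.

Metrics treat *fall* as positive: recall (sensitivity), specificity,
precision, F1, accuracy, AUC-ROC, and maxSeSp. AUC is computed by rank
(Mann–Whitney) pair counting with ties at half credit — equivalent to
trapezoidal ROC integration, and cross-checked against an independent
trapezoid implementation in the tests. maxSeSp — a balanced-operating-
point summary used in the threshold-detector literature — is defined here
as the maximum over all score thresholds of min(Se, Sp); it equals 1
exactly when scores separate the classes, and 0 when all scores tie.
Per-fold metrics that are undefined (e.g. AUC in a single-class test
fold) are recorded as missing and excluded from aggregates with a
warning, rather than silently zeroed; the standalone `confusion_metrics()`
utility instead returns 0 with a warning for zero-denominator ratios, the
conventional degenerate-predictor reading.

Aggregation is per-fold-then-average (mean ± SD across folds), matching
the way such results are conventionally tabulated; pooling predictions
across folds before computing metrics would weight folds by size and
hide fold variance.

Three drivers mirror the questions a multi-source study asks.
`run_within_dataset()`: selection on the dataset, then grouped k-fold.
`run_combined()`: sources concatenated with dataset-qualified subject
keys (duplicate trial rows are an integrity error), selection on the
pooled matrix, grouped k-fold. `run_cross_dataset()`: selection and
training on one full source, a single evaluation on the pooled held-out
sources — pooled rather than averaged per-source, since the deployment
question is "how does this model do on data it has never seen", and a
flag-free single number answers it; per-source results can be obtained by
passing one test dataset at a time.

Selection is run once per experiment on the full experimental matrix
(mirroring common practice) rather than re-run inside every fold; this is
a mild optimism on within/combined estimates, which we accept for
comparability across models evaluated on identical folds and note here
explicitly.

## Problem sizes and runtime choices

The default corpus — 3 sources × 10 subjects × 7 activities × 3 trials ×
15 s, i.e. 630 trials and 8820 windows — is the size at which the full
chain (generation through double 10-fold CV) completes in a few minutes
on one CPU while keeping ≥ 600 fall windows, enough for stable per-fold
recall. Unit and property tests use a 3-activity, 5-subject variant of
the same three-dialect design. These sizes are package choices; every
stage scales to larger configurations through `generator_config()`.

## Known limitations

- Generator realism is structural, not biomechanical; results on it bound
  mechanism correctness, not field performance.
- The `per_dataset` normalization mode leaks test-set extremes by design
  (it mirrors whole-dataset preparation); use `fit_on_train` when leakage
  matters.
- One-at-a-time ablation cannot see grouped redundancy (above).
- The ANN is a deliberately small, fully deterministic trainer; it is not
  a performance-tuned deep model, and momentum can transiently raise the
  loss (the monotonicity guarantee holds for plain gradient descent with
  a small rate).
- `maxSeSp` has no single standard definition in the literature; ours
  (max over thresholds of min(Se, Sp)) is stated prominently so numbers
  are comparable only under the same reading.
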