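---
title: "Sparse logistic regression for multi-tube flow cytometry diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse logistic regression for multi-tube flow cytometry diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The diagnostic problem

Acute myeloid leukemia (AML) screening by flow cytometry produces, for
each patient, seven stained aliquots ("tubes").  Every tube measures
seven channels per cell: forward scatter (FS, a size proxy, linear
scale), side scatter (SS, granularity, log scale) and five fluorescence
channels (FL1–FL5, log scale) carrying the tube's antibody panel.
CD45-ECD occupies FL3 in every tube; each remaining marker appears in
exactly one tube (`aml_panel()`).  An eighth isotype-control tube
carries no diagnostic panel and is excluded everywhere.

The classification unit is the *patient*, not the cell.  Each tube
contributes a summary of its whole event cloud, and a final model fuses
the per-tube summaries into a single confidence of the patient being
AML-positive.  `flowlasso` implements this pipeline end to end,
together with the reference methods it is benchmarked against and a
synthetic cohort generator that makes every stage testable without
access to clinical data.

## The per-tube EDF-MSE summary

**Feature expansion (7 → 84).**  Both the projection and the final
aggregation are linear, so channel interactions are made explicit
up front: the 7 channels are augmented with all inverses (7), squares
(7), unordered pairwise products (21) and ordered pairwise quotients
(42), in a fixed documented column order (`expanded_feature_info()`).
Because log-scaled channels can hit zero, any divisor `d` with
`|d| < eps` is replaced by `sign(d)·eps` (`sign(0) = +1`); `eps`
defaults to `1e-6`, small enough to preserve ordering on these scales
while guaranteeing finite output.  The counts (7 + 7 + 7 + 21 + 42 =
84) are fixed; the *order* within blocks (lexicographic pairs) is this
package's convention, since only the counts are canonical.

**Fisher LDA to one dimension.**  Per tube, the direction
`w = (S_A + S_H)^(-1) (μ_A − μ_H)` maximizes 1-d class separation,
where the class means and covariances of the expanded event clouds are
accumulated **streaming, one patient at a time**
(`streaming_moments()`), so the expanded training data (which easily
reaches gigabytes at clinical event counts) never needs to be held in
memory.  The engineered features make `S_A + S_H` ill-conditioned
(squares and quotients differ by orders of magnitude in scale), so the
solve escalates a ridge along a fixed ladder of *relative* values
(0, 1e-8, …, 1 times the mean covariance diagonal) until the solution
is finite with relative residual below `1e-6`.  A relative ladder was
chosen over an absolute one because the covariance scale is dominated
by arbitrary channel units; the absolute ridge actually used is
recorded in the fitted direction.

**Reference EDFs on a 128-point grid.**  Projected training events are
summarized by empirical distribution functions evaluated at `K = 128`
points uniformly spaced from the minimum to the maximum of the pooled
training projections of *both* classes, so the healthy reference, the
AML reference and any test EDF share one grid.  `K` is configurable;
128 is the default because the comparison is insensitive to modest
changes in `K`.  Per class, the reference is by default the EDF of the
**pooled events** of all its training patients — the simplest reading
of a "population" EDF.  Because patients contribute unequal event
counts, an alternative that weights patients equally (the average of
per-patient EDFs, `reference = "per_patient"`) is offered behind a
flag; both satisfy the same monotonicity and range invariants.

**Similarity scores.**  A test tube's EDF is compared to each class
reference by the mean squared error over the grid, giving two
nonnegative scores per tube and a 14-vector per patient ordered
`t1_healthy, t1_aml, …, t7_aml`.

## The sparse aggregator

The 14 scores (or 49 mean intensities; see below) are z-scored with
training statistics — the scale is the population SD, matching the
fitter's internal standardization, so that coefficient magnitudes are
comparable across features — and fed to a logistic regression whose
coefficients maximize the L1-penalized Bernoulli log-likelihood with an
unpenalized intercept.  The penalty acts as an embedded feature
selector: tubes irrelevant to the diagnosis drop out of the model
entirely, which is the method's practical appeal (fewer tubes to
assay).

The fitter (`fit_l1_path()`) is a glmnet-style iteratively reweighted
least squares loop around cyclic coordinate descent with
soft-thresholding, warm starts along a 100-point log-spaced penalty
grid from `λ_max` (the KKT threshold at which the first coefficient
activates) down to `λ_max × 1e-3`, an active-set strategy, and a
compiled inner loop.  Numerical choices: IRLS weights are clamped below
at `1e-5`, convergence is declared when the largest coefficient change
falls below `1e-8`, and sweeps are capped at `1e5` per penalty.
Solutions satisfy the KKT conditions to `1e-6` and agree with both an
independent box-constrained convex solver and an established
penalized-GLM implementation in the test suite.

`λ` is selected by stratified k-fold cross-validation (default
`k = 10`) minimizing the pooled out-of-fold misclassification rate at
the 0.5 threshold, with ties broken toward the **largest** penalty
(the sparsest model); the final model is the full-data path point at
the selected `λ`.  Stratification is required by the severe class
imbalance of realistic cohorts (e.g. 43 vs 316).  The CV statistics
for the penalty search are always computed inside the surrounding
benchmark's training folds, never on held-out patients, to avoid
leakage.  `best_subsets_report()` extracts, for each support size on
the path, the point with lowest CV error, features ordered by absolute
standardized coefficient.

On balanced pure-noise data this selection rule picks a heavily
regularized model *typically* (the median selected index lies in the
sparse quarter of the grid) but not almost-surely: chance fits beat
the 0.5 error of the empty model often enough that roughly a quarter
of null replicates select below the top quartile.  The tests assert
the typical-behavior form of this property.

## Alternative feature sets and reference methods

* **Mean / LR-LASSO** — the 49 per-tube, per-channel mean intensities
  with the same sparse aggregator.  CD45 and scatter are *not* pooled
  across tubes: pooling was tested in the source study and reduced
  validation performance.
* **Mean / LDA** — the same 49 features with a plain Fisher
  discriminant over patients; a deliberately simple baseline.  Its
  scores have no probability scale, so its decision threshold
  minimizes training error.
* **Moment features / LDA** — six summaries (mean, SD, skewness,
  kurtosis, median, IQR) per channel and tube, 294 features.
  Skewness and kurtosis are plain standardized central moments
  (normal kurtosis = 3, not excess — the convention is recorded in the
  feature labels' documentation); quantiles use linear interpolation;
  constant channels map to zeros by convention.  The originating
  method classified these features with GMLVQ; here they are plugged
  into the same LDA classifier, which keeps the comparison about the
  *features*.
* **KL-histogram (Vilar)** — per tube, four 4-d histograms (each of
  FL1/FL2/FL4/FL5 joined with CD45, FS and SS), 9 bins per dimension,
  events outside any dimension's range discarded as outliers.  The
  classifier sums `KL(test‖healthy) − KL(test‖AML)` over all
  sub-histograms and maps the total through a logistic gain.  The
  original's printed bin ranges are not recoverable, and the method is
  known to be sensitive to them, so ranges are explicit configuration,
  defaulting to the 0.5th–99.5th percentiles of pooled training events
  per tube and channel.  Bin spacing is uniform on the working scale:
  since the pipeline consumes data whose SS/FL channels are already
  log-transformed, linear spacing here corresponds to log-spaced bins
  in raw intensity; genuine log spacing is available for positive
  channels.  Both KL arguments are smoothed additively
  (`alpha = 1e-6`) and renormalized, making the divergence finite and
  exactly zero for identical inputs.  The orientation (test‖reference)
  and the sign convention (higher confidence = more AML-like) are
  package choices; the original's description leaves both ambiguous,
  so a sign flip relative to the original submission is possible.

## Evaluation harness

`run_cv_benchmark()` runs stratified, optionally repeated, k-fold CV
in which *everything* trained — LDA directions, reference EDFs,
histograms, normalizers, penalties — is re-estimated inside each
training fold.  Out-of-fold scores are pooled across folds and
repeats.  Reported metrics: ROC AUC in its Mann–Whitney form (ties
counted ½, identical to the all-pairs count to machine precision), PR
AUC by interpolation-free step summation, confusion matrices at 0.5
for probabilistic scorers (the canonical logistic decision point) or
at the training-error-minimizing threshold otherwise, pairwise DeLong
tests for equality of correlated AUCs, and a challenge-style
separation score, `−log10` of the one-sided Mann–Whitney p-value that
the ranking separation arose by chance (exact tail for small tie-free
samples, otherwise normal approximation with tie correction).  The
original challenge score combined ROC- and PR-based p-values via a
derivation not restated in the available text; the ROC-based score is
used here.

## The synthetic cohort generator

`cohort_spec()` defines per-tube Gaussian mixtures of cell populations
in the already-transformed channel space (the classifiers consume
preprocessed data, so no transformation is simulated).  Defaults:

* two shared base populations per tube — a lymphocyte-like cloud (low
  SS, moderate CD45) and a granulocyte-like cloud (higher FS/SS) — in
  a 60/40 mix;
* an AML-only *blast* population derived from the lymphocyte-like one
  with `+3 SD` shifts on the channels where blasts separate (CD13-PE
  and CD16-PC5 in tube 4, CD34-PC5 and CD38-PC7 in tube 6) and reduced
  side scatter, echoing the markers that dominate trained models on
  the clinical data; fully configurable;
* per-patient blast prevalence drawn from `[0.2, 0.5]`;
* a per-patient random mean shift (SD 0.1 channel units) applied to
  all populations, so patients within a class are not identically
  distributed;
* per-tube event counts uniform in `[6764, 49370]`, the range of the
  clinical cohort; tests and examples scale this down (typically
  100–400 events) purely to bound runtime, which leaves all
  per-patient distributional structure intact while making similarity
  scores noisier than at clinical event counts;
* the `cohort_spec_challenge()` preset fixes the 43/316 class sizes.

What the generator does *not* emulate: cytometer artifacts (doublets,
spillover, autofluorescence), heavy-tailed or skewed subpopulations,
and correlations between tubes beyond the shared patient shift.
Passing tests therefore demonstrate correctness of the algorithms and
sensible behavior under the assumed mixture structure — not clinical
performance.  The headline accuracies of the source study are
computed on an external challenge dataset and are out of scope here.

## Problem sizes used in the shipped studies

The packaged simulation studies use: 100 replicates of a 10/25-patient
cohort in which only tube 4 is informative (support-recovery study);
a 30/120 zero-effect cohort and a 40/160 strong-effect cohort
(calibration and benchmark studies), with 100–400 events per tube and
a 50-point penalty grid down to `λ_max × 1e-2`.  These sizes were
chosen once as the smallest cohorts at which the studied properties
are statistically stable.

## Known limitations

* The per-tube LDA assumes the expanded features have finite second
  moments within class; extremely heavy-tailed channels could make the
  streaming covariance unstable.
* Raw EDF-MSE scores depend on the training grid; scores from models
  trained on different cohorts are not comparable without the stored
  normalizer.
* The KL reference method inherits its original's sensitivity to
  histogram ranges; the data-driven defaults are a pragmatic choice,
  not a reconstruction of the original submission.
* `load_cohort()` flags but does not impute patients with missing
  tubes; all shipped extractors require the full 7-tube panel.
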