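---
title: "Classifying subjects from graph-theoretic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying subjects from graph-theoretic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphfc)
```

## The problem

Resting-state fMRI cohorts are commonly summarised as one ROI time-series
matrix per subject: T time points by N parcellation regions (N = 116 for the
AAL atlas this package takes as its canonical parcellation). The question
graphfc addresses is whether the *topology* of a subject's functional
connectivity network — rather than the raw connectivity values — carries
diagnostic signal that a classifier can exploit, with autism spectrum
disorder (ASD) versus healthy controls (HC) as the motivating two-class
task. Because brain network organisation changes strongly with development,
cohorts are stratified into five age bands before any model is fit:
[5, 10), [10, 15), [15, 20), [20, 30) and [30, ∞) years. The bands are
half-open so that every age from 5 upward belongs to exactly one band; the
top band is unbounded so the partition is total.

The pipeline has five stages, each an exported verb on tidy tables:

1. **Connectivity** (`connectivity_matrix()`): a symmetric N×N association
   matrix per subject, by one of five estimators.
2. **Graph extraction** (`proportional_threshold()`): binarize by keeping
   the strongest fraction of pairwise weights (default 20%).
3. **Graph metrics → features** (`fc_features()`): 7 nodal metrics × N
   nodes + 5 global metrics = 7N + 5 features (817 for N = 116).
4. **Feature selection + classification** (`sffs_select()`, `train_svm()`):
   a sequential forward (floating) wrapper around an SVM selects 10
   features.
5. **Evaluation and comparison** (`cross_validate()`,
   `repeated_cv_compare()`): stratified 10-fold CV metrics, and repeated-CV
   Welch tests with Benjamini–Hochberg correction to compare estimator
   pipelines.

## Connectivity estimators

All five estimators return a symmetric matrix with zero diagonal (the
self-association of a region carries no edge information downstream):

* **Spearman rank correlation** — monotone association, invariant to
  monotone transforms of any regional signal.
* **Percentage-bend correlation** (`beta`, default 0.2) — a robust
  correlation that bends the most extreme `beta` fraction of observations
  in each margin toward the bulk before correlating. `beta` is the
  contamination fraction the estimator is protected against; at `beta = 0`
  no observation is bent, the ψ function is the identity, and the estimator
  reduces exactly to Pearson correlation. 0.2 is the conventional default
  in the robust-statistics literature.
* **Partial correlation** (`ridge`) — pairwise association conditioned on
  all other regions, from the inverse covariance. With fewer time points
  than regions (T ≤ N, which real sites do produce) the sample covariance
  is singular, so a ridge of `1e-6 · trace/N` is added by default in that
  regime; with T > N no ridge is applied unless requested.
* **Sparse inverse covariance** (`lambda`, default 0.1) — an L1-penalised
  precision estimate (graphical lasso, coordinate descent) on standardized
  data, reported in partial-correlation form. `lambda` is on the scale of
  a correlation matrix; 0.1 gives moderate sparsity at the series lengths
  typical of resting-state data. The solver refuses to return a
  non-converged solution and reports its residual instead.
* **Mutual information** (`bins`, default ⌈√T⌉) — equal-width histogram MI
  in nats. MI is nonnegative, so when thresholding MI-based matrices
  together with signed correlations, the `rank_by = "absolute"` threshold
  mode is the natural companion.

Neither the bend fraction, the lasso penalty, nor the MI binning is
prescribed by the underlying study design; all three are exposed as
arguments with the defaults above, chosen once as the field-standard
settings.

## Graph extraction

`proportional_threshold()` keeps exactly ⌊keep_fraction · N(N−1)/2⌋ of the
off-diagonal pairs — `floor` so the stated proportion is never exceeded —
and sets them to 1. For N = 116 and the default 20% this is 1334 of 6670
pairs. Ranking is by *signed* weight by default (the literal "highest
weights" reading: strong anticorrelations are discarded); magnitude
ranking is available via `rank_by = "absolute"`. Ties are broken
deterministically by (weight desc, row asc, col asc), so results are
reproducible even on degenerate inputs; an all-equal weight matrix
triggers a warning rather than an error. Keeping the thresholding
monotone (the edge set at a smaller fraction is a subset of the edge set
at a larger one) and scale-invariant are tested properties.

## Graph metrics and the 817-dimensional feature space

Seven nodal metrics — degree, clustering coefficient, local efficiency,
betweenness centrality (normalized), eigenvector centrality
(max-normalized, computed on the largest connected component with zeros
elsewhere), participation coefficient and within-module degree z-score —
plus five global ones — transitivity, characteristic path length, global
efficiency, mean clustering and modularity Q. This 7 + 5 split is the only
arrangement of the named segregation/integration/centrality families
consistent with a 7N + 5 = 817 feature count at N = 116, and is recorded
here explicitly as an inference; both tables are exposed separately
(`nodal_metrics()`, `global_metrics()`) so other rosters can be assembled.

Disconnected graphs follow the standard conventions: characteristic path
length averages over reachable pairs only, efficiency counts unreachable
pairs as zero contribution, and an edgeless graph reports path length 0.
The participation coefficient and z-score require a module partition;
`detect_modules()` uses Louvain modularity maximisation made deterministic
by an explicit RNG seed, which is part of the feature-table metadata.
Modules with zero degree-SD give z = 0 rather than NaN, so feature vectors
are always finite.

Feature names are `<metric>_<ROI>` in metric-major order with the five
`<metric>_global` entries last; the order is fixed across subjects, runs
and platforms, which the tests assert, because the wrapper selection
tie-break ("lowest canonical index") is only meaningful under a frozen
order. Eigenvector centralities come from an iterative solver, so repeated
runs agree to solver precision (~1e-12) rather than bit-for-bit; names are
byte-identical.

A sixth "concatenation" pipeline (`concatenate_pipelines()`) joins the
five per-estimator tables feature-wise with estimator-prefixed names
(5 × 817 = 4085 features), before any selection.

## Selection and classification

`sffs_select()` implements sequential forward selection with an optional
floating (conditional-exclusion) step, scored by stratified k-fold CV
accuracy of an SVM under one fixed fold assignment. Iteration 1 evaluates
every candidate alone; each later iteration adds the accuracy-maximising
feature. With floating enabled, a previously selected feature is removed
whenever removal strictly beats the best accuracy recorded for the smaller
subset size; both modes exit with exactly `k` features (default 10).

Design points that were genuinely open, and the choices made:

* **Kernel.** The source material is contradictory (a Gaussian kernel is
  named in one place, linear in two others, with overfitting control as
  the stated motive). The default is **linear with C = 1**, the
  anti-overfitting reading; `kernel = "radial"` is available.
* **Scoring folds.** Selection is scored on the same fixed stratified
  folds throughout, which mirrors the described procedure but means the
  selection-stage accuracy trace is optimistically biased as an estimate
  of generalisation; an honest estimate requires evaluating on folds not
  used for selection. The null-calibration test therefore checks the
  *classifier's* CV accuracy on zero-effect data, where no selection is
  interposed.
* **Standardization.** Features are standardized with mean/SD learned
  from training folds only and applied to the held-out fold — the tests
  rely on no other leakage path existing (selection scoring and model
  fitting see training rows only).
* **Ties** are broken by the lowest feature index in canonical order, so
  identical seeds and data give identical selections.

## Evaluation and pipeline comparison

`cross_validate()` reports per-fold confusion matrices (ASD positive) and
pooled accuracy, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), and
the chance level = the majority-class proportion (the accuracy of always
predicting the most populous group). Note the epidemiological definitions
are used: a prose description of sensitivity as "the fraction of positive
*predictions* that are correct" describes precision, not sensitivity, and
is deliberately not what is implemented. Stratified folds put each class's
per-fold count within one subject of proportionality, and remainders are
offset across classes so total fold sizes also differ by at most one
(51 subjects in 10 folds: nine folds of 5 and one of 6).

`repeated_cv_compare()` runs R repetitions of k-fold CV (default 10 × 10)
with the fold assignment of each repetition *shared across pipelines*, and
compares every pipeline pair with Welch's unequal-variance t-test (null:
equal mean accuracy), followed by Benjamini–Hochberg correction over the
pairs, capped at 1. The default test unit is the 10 repetition-mean
accuracies per pipeline: fold-level accuracies within a repetition are
strongly dependent, so repetition means are the least-dependent unit
consistent with a 10-and-10 Welch test; `level = "fold"` switches to the
100-fold-accuracy reading for sensitivity analyses. Degenerate
zero-variance comparisons are handled explicitly (identical samples:
t = 0, p = 1; separated constant samples: p → 0 with a warning) because
`stats::t.test()` refuses essentially-constant data. The corrected
resampled t-test of Nadeau–Bengio, which inflates the variance for
train-set overlap, is a documented alternative that is *not* implemented;
the repeated-CV Welch test is known to be liberal under heavy resampling
dependence.

## The synthetic cohort generator

`simulate_cohort()` exists so every pipeline stage is testable with known
ground truth and no data download. Each group has a generating graph:
modules of ROIs with within-module edge probability `p_within` (default
0.85) and between-module probability `p_between` (0.05); edges carry
target correlation `r_edge` (0.35), non-edges a weak background (0.03).
Subject-level individuality is a small symmetric jitter (SD 0.02) on the
group correlation matrix, repaired to positive definite by eigenvalue
clipping at 1e-6 (and rescaled to a correlation matrix) when an aggressive
configuration requires it — the repair is reported, never silent. Series
are multivariate normal and standardized; ages are drawn to populate all
five age bands; groups are label-balanced.

A group *effect* is a topological alteration of group 2's generating
graph with the altered nodes recorded: `densify_module` completes one
module's edges and raises their correlation by `delta` (a clustering/degree
effect), `rewire_hub` detaches a hub from its module and attaches it
across modules (a betweenness/participation effect). The defaults used in
the end-to-end recovery checks — 60 subjects per group, T = 300 time
points, a within-module correlation difference of 0.3 — represent a
strong, clearly-detectable effect; the null checks use zero effect, where
both groups share one generating graph and are exchangeable by
construction.

What the generator deliberately does **not** model: hemodynamics (the
pipeline consumes only correlation structure, so a Gaussian signal model
is sufficient — but conclusions about BOLD-specific artefacts cannot be
drawn from it), site effects, scanner drift, motion, autocorrelated noise.
Passing the synthetic end-to-end checks shows the machinery is correct and
calibrated under the stated model; it does not show that real resting-state
data contain a recoverable effect.

## Problem sizes and numerical choices in the shipped checks

The package's own validation suite uses deliberately modest problem sizes,
chosen once as the smallest that exercise each property convincingly:
metric correctness is checked against brute-force enumeration exhaustively
over all labelled graphs on up to 5 nodes and on seeded random samples at
6–7 nodes (tolerance 1e-9); estimator consistency on T = 2000 draws from a
5-dimensional AR(1) Gaussian (tolerance 0.05, with the Spearman target
(6/π)·asin(ρ/2) under Gaussianity); null calibration over 20 seeded
zero-effect cohorts of 50 subjects (12 ROIs, T = 120), requiring mean CV
accuracy within 3 standard errors of chance; and effect recovery over 20
seeded cohorts at the full stated effect conditions (60/60 subjects,
T = 300, Δr = 0.3, 12 ROIs), requiring an altered-node feature among the
selected 10 in at least 80% of runs and a mean accuracy gain over chance
above 0.15. The wrapper-recovery unit test counts a run as a hit when at
least 2 of 3 implanted features are selected: informative features built
on a shared group shift are partially redundant, and a greedy wrapper that
has found a separating pair is behaving correctly when it ignores the
third — the 2-of-3 criterion was fixed by pilot runs before being frozen.

## A worked example

```{r example, eval = FALSE}
library(graphfc)

cfg <- simulation_config(
  n_rois = 12, t_timepoints = 200, n_per_group = 30,
  effect = effect_spec("densify_module", module = 1, delta = 0.3),
  seed = 42
)
sim <- simulate_cohort(cfg)

features <- fc_features(sim$cohort, estimator = "spearman")
selection <- sffs_select(features, k = 10, folds = 10, seed = 42)
tidy(selection)

cv <- cross_validate(features, selection, folds = 10, seed = 42)
glance(cv)
autoplot(cv)

# compare two estimator pipelines under shared folds
cmp <- repeated_cv_compare(
  list(
    spearman = features,
    bend = fc_features(sim$cohort, estimator = "bend")
  ),
  k = 10, repeats = 10, folds = 10, seed = 42
)
tidy(cmp)
autoplot(cmp)
```

## Known limitations

* The 7-nodal/5-global metric roster and the concatenation-pipeline
  definition are documented inferences, not prescriptions.
* Selection scored on the evaluation folds is optimistically biased; use
  fresh folds (a different `seed` in `cross_validate()`) for honest
  accuracy estimates.
* Weighted-graph metric variants, dynamic (sliding-window) connectivity
  and small-worldness/rich-club summaries are out of scope.
* The repeated-CV Welch comparison ignores training-set overlap between
  repetitions and is therefore anti-conservative; treat borderline
  corrected p-values with caution.
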