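---
title: "Ensemble SVM-RFE: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SVM-RFE: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The selection model

A linear soft-margin SVM trained on samples $x_i \in \mathbb{R}^p$ with
labels $y_i \in \{-1, +1\}$ yields a primal normal
$w = \sum_i \alpha_i y_i x_i$ over the support vectors. The magnitude of
$w_j$ measures how much feature $j$ contributes to the decision boundary,
so $c_j = w_j^2$ is a natural elimination criterion: removing the feature
with the smallest $c_j$ perturbs the margin least. Recursive feature
elimination iterates fit–rank–drop until a target count $d$ remains.

With tens of samples and thousands of features a single SVM's $w$ is a
high-variance estimate, and under class imbalance it is pulled toward the
majority class. `esvm_rfe()` addresses both at once. At every elimination
step it draws $b$ bootstrap bags that are *class-balanced by construction*
— for each class, a fixed number of rows (by default the minority-class
size) is sampled with replacement from that class — fits one linear SVM
per bag on the surviving features, and aggregates the criteria across the
ensemble:

$$\mathrm{total}_j = \sum_{m=1}^{b} w_{j}^{(m)\,2}.$$

The fraction $E$ of surviving features with the smallest totals is
eliminated and the loop repeats until exactly $d$ survive. For $k > 2$
classes each bag is fitted as all $k(k-1)/2$ one-vs-one binary problems
and $c_j$ sums the squared weights across pairs; this is our reading of
the weight-based criterion for multiclass output, where the one-vs-one
dual coefficients do not define a single hyperplane.

Classic single-model SVM-RFE is the degenerate configuration `bags = 1`,
`resample = FALSE` (`svm_rfe()`), which the test suite verifies against an
independently written brute-force refit-and-argmin loop.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `bags` ($b$) | SVMs per elimination step | 40 | diminishing returns beyond a few dozen; rankings from a deterministic base learner become redundant |
| `elim_frac` ($E$) | fraction of survivors dropped per step | 0.10 | trades ranking granularity against the number of ensemble refits |
| `n_features` ($d$) | surviving-feature target | 1 | $d = 1$ yields a complete ranking |
| `bag_spec` | per-class bootstrap counts | minority size per class | the smallest rule that guarantees exactly balanced bags without synthesizing samples; can be overridden, e.g. biased toward the minority class |
| `cost` (C) | SVM soft-margin cost | 1 | data are z-scored upstream, so the solver default scale is appropriate; no internal rescaling is applied inside the ranker, which would silently double-normalize |

The elimination schedule removes $\lfloor mE \rfloor$ of the current $m$
features but always at least one (otherwise $mE < 1$ would stall the loop)
and never past $d$ (the final step is clipped so runs terminate at exactly
$d$). Ties in the totals are broken by original feature index, so runs are
reproducible across platforms. The full ranking orders the $d$ survivors
by their final totals and appends eliminated features in reverse
elimination order, within a step by that step's totals — the only evidence
available at the time each feature was dropped.

One RNG stream, seeded once, drives all bags of all iterations
sequentially; a single integer reproduces an entire run bit-for-bit
(the command-line `rank` subcommand's outputs are byte-identical under a
repeated seed, and each run writes a manifest with the resolved
configuration).

## Preprocessing and splitting

Features are z-scored with the sample standard deviation ($n-1$). When a
train/test split exists, test data are normalized with the *training*
means and standard deviations (`zscore_normalize(test, stats = ...)`) to
avoid test-information leakage; the package never recomputes statistics on
held-out data. Zero-variance features become all-zero columns rather than
being dropped, keeping feature indices stable for ranking; their criterion
is exactly zero, so they are eliminated first.

`stratified_split()` holds out a fixed fraction (default a quarter) with
per-class counts set by largest-remainder rounding of
$n_c \times \text{fraction}$, constrained to a total of
$\mathrm{round}(n \times \text{fraction})$. Every class is therefore
within one sample of exact proportionality. For a 21:39 two-class cohort
of 60 this gives the expected 45 training and 15 test samples.

## Evaluation protocol

* **Choosing $k$**: `loo_select_k()` evaluates candidate feature counts by
  leave-one-out cross-validation on the training set, scoring each
  held-out sample with the SVM decision value (not the hard label — AUC on
  binary predictions is needlessly coarse) and selecting the smallest $k$
  attaining the maximum AUC (parsimony; a larger subset with the same LOO
  AUC has no evidence in its favour).
* **Test performance**: `bootstrap_test_auc()` refits the SVM on $B$
  uniform full-size bootstrap resamples of the training set and evaluates
  each on the fixed held-out test set, summarizing the $B$ AUCs as
  min/Q1/median/mean/Q3/max with R's default type-7 quantiles. Resamples
  that come up single-class are redrawn (at most ten attempts). This is
  repeated bootstrap training with a fixed test set — it does not apply
  the Efron–Tibshirani .632+ weighting, which combines resubstitution and
  out-of-bag error instead of using a held-out set.
* **Comparing selectors**: two selectors are compared on *shared*
  resamples (same seed), making the per-resample AUC differences paired;
  `paired_auc_ttest()` is the two-sided paired t-test. An exactly constant
  non-zero difference is reported as $p = 0$ rather than erroring, and
  identical vectors are rejected as degenerate.
* **AUC**: `auc_binary()` uses the Mann–Whitney midrank formulation, which
  equals pair counting with ties worth 1/2 exactly; the suite checks this
  identity to 1e-12. Multiclass AUC is macro-averaged one-vs-rest over the
  summed one-vs-one decision values — one of several defensible
  conventions, fixed here so summaries are comparable across runs.

## SVD view

`svd_project()` column-centers the selected submatrix before the thin SVD,
so the 2-D sample scores $U_k \Sigma_k$ form a PCA-style separation view;
uncentered SVD would devote the first axis to the grand mean. Held-out
samples are projected by centering with the *training* means and
multiplying by the training right singular vectors, so training samples
passed back through `predict()` reproduce their coordinates exactly. Each
right singular vector's sign is fixed (largest-magnitude entry positive)
for deterministic plots.

## The synthetic generator

`make_synthetic()` emulates what these cohorts look like at the level the
selector sees: $n \ll p$, 2–8 classes, optional imbalance, and a small
planted set of informative features. Background features are i.i.d.
Normal$(0, \sigma^2)$; informative features receive class mean shifts of
$\pm\Delta/2$ (equally spaced spanning $\Delta$ for more classes). The
defaults — a 21:39 two-class cohort of 60 samples, $p = 2000$, 30
informative features at $\Delta = 1\sigma$ — mirror a small relapse study
measured over a couple of thousand probes: moderate univariate effects,
realistic imbalance, and problem sizes on which the full pipeline runs in
seconds to minutes on one core.

What the generator deliberately omits: feature correlation (an optional
structure would make elimination harder), probe- and batch-effects, and
heteroscedastic noise. Tests passing on this model therefore demonstrate
the *algorithmic* contracts — balanced bagging, aggregation, schedule,
protocol arithmetic — and ranking behaviour under an idealized signal;
they do not certify performance on real microarray noise.

A measured limitation worth stating plainly: on independent features with
10 planted effects of $\Delta = 1.5\sigma$ among 500 ($n = 30{+}30$), the
ensemble's mean top-10 recall over 20 generator seeds is about 0.75 —
clearly above plain SVM-RFE under the same conditions (about 0.65, and the
gap widens under 45:15 imbalance, 0.73 vs 0.65), but short of recovering
the full planted set. The loss is attributable to backward elimination
itself at this effect size: a single SVM's squared-weight ranking *without*
elimination recovers ~0.98 of the planted set, and an independent RFE
implementation (scikit-learn's) shows the same elimination-induced drop on
identical data. The ensemble mitigates, but does not remove, the risk of
discarding a weakly-weighted informative feature early.

## Numerical choices and degenerate inputs

* Solver: libsvm via `e1071`, termination tolerance the solver default
  (1e-3), no class weighting inside the SVM — balance is the bagging's
  job. The dual–primal identity $w = \sum_i \alpha_i y_i x_i$ is verified
  in the tests against an interior-point QP solve with exact active-set
  refinement; agreement is ~1e-7 on margin-separated problems at a
  tightened solver tolerance, and at the 1e-3 level on heavily overlapping
  classes where libsvm stops at its iteration cap — the identity holds to
  the solver's own precision.
* Single-class bags cannot occur under the balanced default (all per-class
  counts ≥ 1); with user-supplied specs they are redrawn up to ten times,
  then error.
* Missing expression values are rejected at load time by default
  (per-feature mean imputation is opt-in); a class with one sample cannot
  be stratified-split and errors with the class named.
* LOO folds whose remainder is single-class (only possible on degenerate
  tiny inputs) error rather than returning a meaningless AUC.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data:
unit checks use toy problems ($n \le 30$, $p \le 40$), the recovery studies
use $p = 500$ with 20 generator seeds, and the end-to-end pipeline uses the
generator defaults ($60 \times 2000$). These sizes were chosen so a full
run of everything completes in minutes on a single core while keeping the
$n \ll p$ regime that motivates the method.
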