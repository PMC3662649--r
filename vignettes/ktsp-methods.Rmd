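---
title: "K-TSP prognostic classifiers: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-TSP prognostic classifiers: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktsp)
```

## The model

A top-scoring pair classifier reads a single bit per gene pair and sample:
whether gene *a* is expressed strictly below gene *b* within that sample's
profile. For binary prognosis classes (poor = recurrence within the study
horizon, fixed as the positive class; good = no recurrence) the switch
score of an unordered pair is

$$\delta_{ab} = \left| \hat P(X_a < X_b \mid \text{poor}) -
\hat P(X_a < X_b \mid \text{good}) \right|,$$

with unweighted empirical class-conditional proportions. $\delta = 1$
means the ordering reverses perfectly between classes; $\delta = 0$ means
the pair carries no class information. Because only within-sample
orderings enter, every quantity in this package — pair ranking, selected
model, vote scores, calls — is invariant under any strictly increasing
transformation applied per sample profile. That invariance is the point
of the method: it removes the dependence of the decision rule on
normalization and preprocessing pipelines, which is where multi-gene
signatures usually lose reproducibility.

The K-TSP ensemble selects K gene-disjoint pairs greedily: score all
pairs, take the best, remove its two genes, rescore the remaining genes,
repeat. Each selected pair votes "poor" when a new sample shows the
ordering that was more frequent in the poor class at training time; the
prognostic score is the number of poor votes in $0..K$, and a sample is
called poor when the score reaches the vote threshold $\tau$.

### Choosing K and $\tau$

For every K in a configured window the training vote scores are computed
and the admissible thresholds are those with training sensitivity exactly
1 — i.e. $\tau \le \min(\text{poor-class scores})$. Among admissible
$(K, \tau)$ the pair maximizing training specificity is selected; for a
fixed K this is simply the largest admissible $\tau$, since specificity
is non-decreasing in $\tau$. Resubstitution estimates are used *only* for
this selection. The vote score is a sum of K binary comparisons, a far
smaller hypothesis space than continuous-score classifiers, which is why
resubstitution is tolerable here for model selection; it is still
optimistic, and the package never reports it as a performance claim (the
test suite quantifies this optimism on null cohorts: training AUC on
unstructured data sits above 0.5).

The AUC-versus-K curve is additionally computed for $K = 1..15$ (capped
by gene capacity) and stored in the model metadata for inspection,
because the window for selection is usually chosen near the peak of that
curve. The default selection window is $K \in [6, 10]$, the peak region
for a signature-sized panel of ~70 genes; both the window and the curve
range are user-configurable, and the curve bound is a convention rather
than part of the selection rule.

## Deterministic ordering and numerical choices

* **Strict comparisons everywhere.** A tie $X_a = X_b$ counts as "not
  less than" in scoring and votes "good" in classification: a tie is the
  absence of the poor-indicating ordering. This keeps the whole pipeline
  deterministic on data with ties (users who prefer randomized
  tie-breaking can jitter beforehand). One consequence used by the test
  suite: a sample with a constant profile ties every pair, scores 0, and
  therefore makes the 100%-sensitivity constraint infeasible if labeled
  poor — reported as a model-selection failure with per-K diagnostics,
  not silently worked around.
* **Tie-break score $\gamma$.** Pairs with equal $\delta$ are ordered by
  $\gamma_{ab} = |\overline{d}_{\text{poor}} - \overline{d}_{\text{good}}|$
  where $d = \text{rank}(a) - \text{rank}(b)$ with average ranks within
  each sample profile, then by lexicographic gene identifiers (C locale),
  giving a total order. $\delta$ ties are common — $\delta$ lives on the
  lattice $\{i/n_\text{poor} - j/n_\text{good}\}$ — so the secondary
  score does real work. $\gamma$ values are rationals with denominator
  $2\,n_\text{poor} n_\text{good}$; they are rounded to 9 decimals so
  that mathematically equal scores compare equal regardless of floating-
  point summation order (true distinct values differ by at least
  $\sim 10^{-4}$ at realistic cohort sizes, many orders above the
  rounding).
* **Rescoring after removal.** Greedy selection rescores the surviving
  genes at every step rather than filtering the initial ranked list.
  $\delta$ depends only on the two member genes, but $\gamma$ uses ranks
  within the surviving profile, so the two procedures are not equivalent;
  the literal remove-and-rescore loop is the one implemented and the one
  the brute-force test oracle reproduces.
* **Orientation at $\delta = 0$.** Such a pair shows no class preference;
  its orientation is recorded as `"none"` and it always votes good,
  avoiding spurious poor-prognosis calls. These pairs sort last among
  equals and are never selected in practice.
* **$(K, \tau)$ ties.** Equal specificity is resolved by smallest K, then
  largest $\tau$: parsimony first.
* **AUC.** Computed as the normalized Mann–Whitney statistic with ties
  counted one-half (midranks); the ROC curve enumerates all integer
  thresholds $K{+}1..0$ in decreasing order so TPR and FPR are monotone,
  and its trapezoidal area equals the Mann–Whitney form exactly — the
  test suite asserts agreement to $10^{-12}$ and cross-checks against an
  independent ROC library.
* **Bootstrap CI for the AUC.** The method behind published AUC intervals
  for this kind of test is typically unstated, so the package makes its
  choice explicit: percentile interval over resamples stratified by class
  (class sizes preserved), default 2000 resamples, seed required and
  recorded in the report. Percentile intervals can fail to cover the
  point estimate in extreme cases; they were chosen for transparency, not
  optimality.
* **Survival.** The Kaplan–Meier product-limit estimator and the
  two-group log-rank test (hypergeometric $(O-E)^2/V$ with 1 df) are
  implemented directly from their definitions and verified in tests
  against the survival package and hand-computed tables. Cox regression
  is deliberately not wrapped: it is routine and available off the shelf.

## What the synthetic generator emulates

`generate_cohort()` produces a two-class expression cohort shaped like a
small discovery study: by default 70 genes and 34 poor / 44 good samples
(a 78-sample cohort split at a 5-year recurrence endpoint). Background
values are i.i.d. $N(0, \texttt{noise\_sd}^2)$ (default sd 1), making
background genes exchangeable so any background pair has expected
$\delta = 0$. A planted pair occupies a fixed gene slot; for each sample
its ordering is Bernoulli with the class-specific probability
$(p_\text{poor}, p_\text{good})$ — default $(0.95, 0.05)$, a strong
switch — and the pair's two Gaussian draws are assigned sorted or
reverse-sorted to match, so the ordering probabilities are exact by
construction while marginal scales stay comparable to the background.
`generate_survival()` adds exponential event times with a class hazard
ratio and independent exponential censoring.

What this deliberately does not emulate: correlated co-expression
structure, array-intensity distributions, dye effects, housekeeping-gene
normalization, batch effects, or class-imbalance pathologies of real
cohorts. Passing tests on these cohorts therefore demonstrates
algorithmic correctness (scores, selection, thresholds, metrics, and
their invariances), not clinical performance; validating a trained
signature still requires an independent real cohort, which is out of
scope here.

## The published signature fixture

The published 8-pair signature drawn from a 70-gene breast-cancer panel
uses 16 distinct genes: four pairs mix a good-prognosis-associated gene
with a poor-associated one, four pairs use poor-associated genes only.
The pairing diagram itself is not available in machine-readable form,
so `published_signature_genes()` ships the membership with pair
partners marked `unknown` rather than guessing; the accessor exists for
reasoning about assay requirements (8 pairs, 16 genes, $\tau = 2$ in the
published rule), and a hand-written 8-pair, $\tau = 2$ model file is
exercised in the test suite to show such a model loads and predicts.

## Problem sizes used by the test suite

The suite runs entirely on generated data: oracle-equivalence checks use
100 random instances of up to 12 genes and 30 samples against explicit
double-loop re-implementations; invariance checks use 20 seeded cohorts
of 20 genes; planted-pair recovery uses 200 replicates at 70 genes and 40
samples per class; AUC identity uses 1000 random score vectors; log-rank
calibration uses 500 replicates at 50 samples per group with a
Kolmogorov–Smirnov uniformity check. These sizes were chosen to give the
properties real statistical teeth while keeping a full run in well under
a minute per file on a single CPU.

## Known limitations

* Binary endpoint only; no multi-class labels and no calibrated
  probabilities beyond the integer vote score.
* Resubstitution-based selection is optimistic by nature; the package
  treats it strictly as a selection device.
* The log-rank implementation covers the standard unweighted two-group
  test; weighted variants and competing risks are not included.
* Ties are handled by a fixed deterministic policy, which slightly favors
  "good" calls on heavily discretized data.
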