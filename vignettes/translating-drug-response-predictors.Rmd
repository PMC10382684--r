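---
title: "Translating cell-line drug-response predictors to patient tumours"
author: "drtrans maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating cell-line drug-response predictors to patient tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drtrans)
```

## The problem

Drug-response labels for patients are scarce, while large cell-line screens
(hundreds of lines per drug, with IC50-derived sensitive/resistant calls)
are abundant. A classifier trained on cell lines (the *source* domain) and
applied to patient tumours or patient-derived xenografts (the *target*
domain) faces two distinct failure modes:

1. **Covariate mismatch.** Many genes are expressed differently in vitro
   and in vivo; a model that leans on them transfers noise
   (*negative transfer*).
2. **Class-prior shift.** The responder fraction in a screening panel
   rarely matches the responder fraction in a treated cohort, so even a
   perfectly transferred probability model is systematically mis-thresholded
   at 0.5.

`drtrans` addresses both. The feature-selection pipeline keeps only genes
whose *class-conditional* distributions agree across domains, and a
closed-form correction moves the decision threshold from 0.5 to
`r/(r+1)`, where `r` is the ratio of responder odds between the domains.

## The selection pipeline

For each gene `X_i` with binary response `Y` (1 = sensitive, 0 =
resistant), three stages run in order:

1. **Supervised domain-adaptation (DA) filter.** Two two-sample
   Kolmogorov–Smirnov tests per gene compare source versus target values
   within the sensitive class and within the resistant class. A gene
   passes only when *both* p-values are at least `alpha`
   (`ksRule = "both"`, the default). This is the stricter of the plausible
   readings — one could also demand only one side (`"either"`) or pool the
   classes (`"pooled"`); both variants are exposed but not default. Note
   the unusual direction: a *large* p-value is the desirable outcome, so
   `alpha` is a similarity bar (0.6–0.9), not a significance level. The
   filter is deliberately stringent: under exchangeability a gene passes
   both tests with probability near `(1 - alpha)^2`, roughly 5–10% at
   `alpha = 0.7`, which is why realistic inputs are panels of thousands of
   genes.
2. **Differential-expression prioritisation.** Surviving genes are ranked
   by a Welch two-sample t-test (sensitive vs resistant, *source data
   only* — target expression influences nothing but the DA filter) with
   Benjamini–Hochberg adjustment, keeping at most 1,000 genes. Welch
   rather than pooled-variance because group sizes can be as lopsided as
   680 versus 186.
3. **BW-ratio ordering.** The retained genes are sorted by the ratio of
   between-group to within-group sums of squares,
   `BW = sum_k n_k (xbar_k - xbar)^2 / sum_k sum_{i in k} (x_i - xbar_k)^2`.
   Degenerate cases keep the order total: `0/0` scores 0 (ranked last),
   positive-over-zero scores `Inf` (ranked first). Ties break by FDR and
   then gene identifier, so rankings are permutation-invariant.

Small-sample care: KS p-values are computed exactly (conditional on ties)
whenever both sides of a comparison have at most 10 samples — test cohorts
contain as few as 3 responders, where the asymptotic tail is unusable.
This is also why `tests/` validates the p-values against a brute-force
enumeration over all class-preserving splits.

## Predictors

**LogitDA** is logistic ridge regression on the top-`p` ranked genes. The
objective is the *mean* negative log-likelihood plus `lambda * ||beta||^2`
with an unpenalised intercept, solved by damped Newton iterations to a
gradient max-norm below 1e-8. The mean scale makes `lambda` comparable
across training sets of different sizes; the intercept stays unpenalised
because the prior-shift correction acts on the intercept scale. `lambda`
is tuned by a two-stage grid: 11 exponents from `10^-3` to `10^0` in steps
of `10^0.3`, then 11 exponents within ±0.05 of the stage-1 winner in steps
of `10^0.01`. `p` ranges over 50(10)200, 220(20)400, 500(100)1000 by
default. Model selection maximises the mean AUC of stratified 5-fold
cross-validation repeated 10 times; ties prefer smaller `p` (parsimony)
and then smaller `lambda`. Folds are stratified by class — with 28
responders among 370 lines, unstratified folds go degenerate — and every
candidate is scored on identical fold assignments from a seeded generator,
so the whole selection table is bit-reproducible.

**KNNDA** replaces the linear model with a K-nearest-neighbour vote under
the distance `1 - rho` (Spearman's rank correlation between two samples'
expression profiles); Euclidean distance is dominated by platform-level
scale effects that rank correlation ignores. A sample's score is the
fraction of its K nearest training samples labelled sensitive; K ranges
over the odd numbers 3–29 (odd K avoids half-vote ties, and distance ties
break by sample order). Ties in (p, K) selection prefer smaller K, then
smaller `p`.

For scaled-down simulation studies, `trainingConfig(lambda_fixed = ...)`
bypasses the two-stage search; the protocol itself is unchanged.

## The cutoff adjustment

Let `r = (P_S(Y=1)/P_S(Y=0)) / (P_T(Y=1)/P_T(Y=0))` be the odds ratio of
the two domains. When the selected features are domain-invariant and
class-conditionally independent, a source-trained probability applied to
target samples is overestimated for `r > 1` and underestimated for
`r < 1`; thresholding at `r/(1+r)` instead of 0.5 compensates exactly, and
`r = 1` recovers 0.5. The package estimates `r` from the empirical label
counts of both domains (for a test cohort this uses the test labels — the
same information the supervised DA filter already uses; an externally
estimated prior can be supplied instead by passing synthetic label
vectors). Cutoffs are stored at full precision and rounded to two decimals
only for display. The correction presumes a continuous probability score,
so it applies to LogitDA only; `runPipeline()` refuses to combine it with
KNNDA, whose vote fractions are not calibrated probabilities. Scores
exactly at the cutoff classify as 0 (strict inequality), keeping the
conventional behaviour at 0.5.

Because the adjustment needs nothing but four counts, the full set of ten
published cutoffs ships as a worked example: `drugResponseCounts()`
returns the responder/non-responder counts of ten drug cohorts, and
`scripts/acceptance.R` recomputes every cutoff from them at run time.

## The synthetic generator

`generateDomainPair()` draws the two domains with known ground truth.
Invariant genes have the same law given the label in both domains —
Gaussian with a class-mean shift of `effect_size` s.d. for informative
genes (signs alternating, so the optimal logit is not all-positive), pure
noise for null genes. Shifted genes model negative transfer: in the
*source* they carry a class effect of `spurious_effect` s.d. (default
equal to `effect_size`), so differential expression alone cannot tell them
from true markers; in the *target* their mean is offset by `shift_size`
s.d. and carries no class signal at all. A gene that merely shifted its
mean without any source association would never be selected in the first
place and would make the ablation comparison vacuous — the spurious source
effect is what gives the DA filter something real to remove (set
`spurious_effect = 0` for plain nuisance offsets). A `heavy_tails` option
swaps the noise for scaled t(3) draws to stress the KS filter, and
`var_inflation` adds a variance mismatch to shifted genes.

Defaults — 200 samples per domain, 50 informative / 100 null / 500 shifted
genes, `effect_size = 1`, `shift_size = 3`, equal responder proportions —
are the package's standing simulation conditions and are used as such by
the test suite. Labels are redrawn until both classes appear, so every
downstream operation is defined even at small `n`.

What the generator does *not* emulate: gene–gene correlation, batch
structure, platform noise, or any relation between effect size and
expression level. Passing tests therefore demonstrate correctness of the
machinery and the direction of the theoretical effects, not clinical
performance on real cohorts.

## Simulation studies in the test suite

The acceptance tests recompute, at deliberately modest sizes chosen to
keep the suite fast while leaving no directional ambiguity:

* **Over/under-estimation.** With 5 invariant informative genes,
  `n_source = 300`, `n_target = 200`, and `r = 5` (or 0.2), the mean
  source-trained probability exceeds (or falls short of) the target
  responder fraction in every one of 20 seeds.
* **Calibration at `r = 1`.** With matched priors and near-unpenalised
  fits at `n_source = 2000`, decile-binned target scores match empirical
  responder rates within Monte-Carlo error.
* **Accuracy gain.** For `r` in {0.05, 0.2, 5, 20}, 100 seeds at
  `n_target = 200`: mean accuracy at `r/(1+r)` is at least that at 0.5.
* **Recovery and rejection.** On a 50-informative / 500-shifted panel at
  `alpha = 0.7`, the top-50 ranked genes are ≥80% true invariant markers,
  and ≥95% of strongly shifted genes (`shift_size = 5`) fail the filter.
* **Ablation direction.** On shift-heavy panels (the generator defaults),
  the paired with-DA minus without-DA target AUC is positive — mean gain
  ≈ 0.35 across 20 data seeds with a reduced grid (`p_grid = {5, 15}`,
  fixed `lambda = 0.1`, 2 CV repeats).

Simulated pairs are compared with `harmonize = "none"`: the generator has
no global batch effect, and per-domain location–scale matching would
partially absorb the very shift the filter is supposed to detect. On real
cross-platform data, harmonise (or batch-correct upstream) first.

## Known limitations

* The DA filter consumes target labels. That is the supervised-DA design —
  the practical reading is that a handful of labelled target samples buys
  feature portability — but it means target AUC estimates are not fully
  out-of-sample with respect to feature selection.
* With gene panels in the hundreds, the stringent two-test pass rule can
  leave very few survivors; `selectFeatures()` errors with advice rather
  than silently training on an empty panel.
* `r` estimated from small test cohorts is noisy; the cutoff inherits that
  noise. Zero counts in any class make the adjustment undefined, and the
  package refuses rather than extrapolates.
* The location–scale harmoniser matches first and second moments only; it
  is not an empirical-Bayes batch correction.
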