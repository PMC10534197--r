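---
title: "Constructing and validating epigenetic age clocks with cetaclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating epigenetic age clocks with cetaclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetaclock)
```

## The model

An epigenetic clock is a sparse linear predictor of chronological age
from DNA methylation. For a sample with beta values $\beta_j \in [0,1]$
(the methylated fraction at CpG probe $j$),

$$\widehat{\mathrm{age}} = b_0 + \sum_j b_j\,\beta_j,$$

with coefficients in years per unit beta. Clocks are fitted by elastic-net
regression: minimize

$$\frac{1}{2n}\sum_i\big(y_i - b_0 - x_i b\big)^2 +
  \lambda\Big[\alpha\lVert b\rVert_1 + \tfrac{1-\alpha}{2}\lVert b\rVert_2^2\Big],$$

where $y$ are reference ages (here, tooth growth-layer-group estimates),
$\alpha \in [0,1]$ mixes lasso ($\alpha = 1$) and ridge ($\alpha = 0$)
penalties, and $\lambda \ge 0$ sets the overall penalty strength. The L1
component produces the sparsity that makes a clock portable — a handful of
CpGs rather than the whole array — while the L2 component stabilizes
selection among correlated probes.

Assumptions worth keeping in mind: methylation trends are treated as
linear in age on the beta scale over the observed age range (no log-age
warping — clocks here may legitimately predict small negative ages for
fetal or neonatal samples); training ages are treated as exact even though
tooth readings carry their own error; and samples are treated as
independent, so serially sampled individuals should contribute one
training record.

## Fitting conventions

`fit_elastic_net()` delegates the optimization to `glmnet`, the standard
tool for this model class, under the following conventions:

- **Standardization.** Predictors are centered and scaled to unit
  variance inside the optimizer; coefficients are reported back on the raw
  beta scale, so a fitted clock applies directly to normalized betas. The
  intercept is never penalized.
- **Penalty path.** 100 geometrically spaced $\lambda$ values from
  $\lambda_{\max}$ (the smallest penalty with an all-zero solution) down
  by a factor $10^{-4}$.
- **Penalty selection.** Internal 10-fold cross-validation minimizing
  mean squared error, with fold assignment drawn once from the
  specification's seed ("lambda-min" rule). The `lambda_rule = "1se"`
  switch selects the more conservative one-standard-error penalty
  instead. Fold labels are shared across all candidates of a grid search
  so that models differ only in their hyperparameters, and a fixed seed
  makes every fit — and hence the whole candidate grid — bit-reproducible.
- **Fixed-penalty solves.** When `lambda` is supplied explicitly,
  cross-validation is skipped and the solver is run down a warm-start path
  terminating exactly at the requested penalty. Because the optimizer's
  internal response scaling divides the quadratic penalty by the
  population standard deviation of $y$, the requested $(\lambda, \alpha)$
  is first converted into the solver's parameter space; the returned
  solution then minimizes the objective exactly as written above. The
  test suite verifies this against brute-force grid minimization, the
  least-squares limit ($\lambda \to 0$), and the ridge closed form
  ($\alpha = 0$).

## The pipeline

A typical construction run is: filter probes by detection support, search
the $(\alpha, \text{threshold})$ grid, select a parsimonious model,
confirm by LOOCV, and screen for confounders.

**Detection filtering** (`filter_probes_by_detection`) keeps CpGs whose
detection p-value is strictly below 0.05 in at least $k$ training
individuals ($k \in \{10, 20, 30\}$ by convention, plus the unfiltered
set). Retained sets shrink monotonically as $k$ rises; this is asserted as
a property test. Per-CpG p-values are used raw — no multiple-testing
correction is applied, since the counts feed a hard filter rather than an
inferential claim; users comparing significance counts across datasets
should keep this in mind.

**Grid search and selection.** `alpha_grid_search()` fits one
cross-validated clock per $(\alpha, k)$ cell ($\alpha$ from 0.1 to 0.9 in
steps of 0.1 by default) and scores it in-sample; LOOCV is reserved for
confirming the selected recipe rather than driving the search, keeping
the expensive step out of the inner loop. `select_model()` then returns
the sparsest candidate whose median absolute error is within
`medae_tolerance` (default 0.5 years) of the grid optimum, breaking ties
toward larger $\alpha$ and larger $k$. This encodes the working
preference for clocks that are accurate *and* small: among near-equal
candidates, fewer CpGs means cheaper assays and less overfitting.

**LOOCV** (`loocv`) refits the entire recipe — including the detection
filter — on every leave-one-out training set, so no information from the
held-out sample leaks into probe selection. The `refilter = FALSE` switch
reproduces the optimistic variant that filters once globally, for
comparison with analyses that did so. Folds are processed in sample-id
order with the seed reset per fold, making held-out predictions invariant
to input ordering.

**Confounder screening** (`confounder_screen`) fits a binomial elastic
net ($\alpha = 0.5$, cross-validated binomial deviance) of a binary
nuisance label — subspecies, tissue source — on all probes and reports the
CpGs it selects. Here the penalty defaults to the one-standard-error rule
rather than the deviance minimum: a screen is a specificity instrument,
and under the minimum-deviance rule a label-permuted (null) screen
frequently selects a few noise CpGs, while the 1-SE rule leaves null
screens empty in most seeds. Age-clock fits keep the lambda-min
convention. `check_clock_confounding()` then intersects a clock's CpG set
with each screen; any overlap flags the clock as potentially encoding the
confounder rather than age.

**Missing data policy.** Stored beta matrices may contain missing values,
but training drops any probe with a missing beta in the training set —
the simplest defensible rule, since penalized fits cannot tolerate
missing predictors and imputation would invent methylation. At
prediction time the policy is explicit: `missing_policy = "error"`
(default) names the offending probes, `"skip_sample"` yields `NA` for
affected samples.

**Joint training sets.** `merge_training_sets()` pools two studies over
the intersection of their probe universes, concatenating samples without
adding a species covariate — the joint clock must explain both species
with one set of coefficients, which is what makes it transferable.

## Cohort analysis

`age_structure()` compares predicted age distributions between survey
periods with the Wilcoxon rank-sum test, reporting the Mann–Whitney $U$
statistic (the convention of `wilcox.test`, so values are comparable
across analyses). The in-package implementation enumerates the exact
permutation null — including tied data, via midranks — whenever the
instance is small enough (all label assignments when
$\binom{n}{n_x} \le 10^5$, the closed-form tie-free null for
$n_x n_y \le 400$), and otherwise uses the normal approximation with tie
and continuity corrections. The paired `wilcoxon_signed_rank()` follows
the same scheme over sign patterns ($2^n$ enumeration for $n \le 16$).
Exactness is verified in the tests against full brute-force enumeration
on every small instance shape.

By default each individual contributes one age per period (the
latest-dated sample) to avoid pseudoreplication from repeated biopsies;
`per_sample = TRUE` keeps every biopsy event. Bootstrap CIs for the period
means use 10,000 seeded percentile resamples. Negative predicted ages are
reported as-is. `serial_consistency()` checks that individuals sampled
years apart are predicted older at the later sampling, pairing
consecutive samples and comparing predicted with calendar intervals.

## The synthetic generator

`generate_synthetic()` emulates what the pipeline needs from normalized
array data, without reproducing array chemistry:

- **Age link.** Informative CpG $j$ has mean
  $\mathrm{logit}^{-1}(a_j + s_j\,\mathrm{age})$, keeping betas in range
  without truncation dominating; clipping to $[0,1]$ is a safety net
  only. Slope magnitudes are drawn around `slope_scale` (default 0.15
  logit/year, about 3 logits across a 20-year span — strong but
  realistic for clock CpGs) and crossing ages sit in the middle half of
  the age range.
- **Sign balance.** A `frac_positive` share of informative slopes is
  positive, split deterministically (`round(frac_positive * n)`), so the
  generator emulates the observed mixture of hyper- and hypo-methylating
  age CpGs with exact, testable counts.
- **Noise and detection.** Gaussian beta-scale noise (default sd 0.02,
  comparable to well-normalized array replicates) and independent
  per-measurement detection failures (default 5%, drawn so failures have
  detection p > 0.05).
- **Confounders.** An optional batch effect shifts a set of background
  probes in the label-1 group, emulating a species or tissue signature
  for screening tests.
- **Defaults** (60 samples, 2000 probes, 8 informative CpGs, ages
  0.25–20 years) mirror a small-cetacean training study: a few dozen
  tooth-aged animals, a sparse age signal, and a dolphin-scale lifespan.

What the generator does *not* emulate — genomic autocorrelation between
neighboring CpGs, probe-specific chemistry biases, normalization
artifacts, age-estimate error in the training labels — bounds what
passing tests show: they demonstrate that the pipeline recovers a known
sparse age signal under realistic noise, not that any particular real
dataset meets these assumptions.

For power analyses of period comparisons, cohort ages are simulated
Gaussian with sd 1.5 years around period means — the within-period spread
under which a 1.1-year shift (the magnitude of interest for a
short-lived dolphin population) is reliably detectable at $n = 40$ per
period.

## Problem sizes used by the test suite

Unit tests run on small fixtures (tens of samples, 40–400 probes). The
end-to-end recovery check uses the generator's default study shape — 60
training samples and a 30-sample holdout at 2000 probes with 8 planted
CpGs, over five seeds — with the grid searched across $\alpha$ at the
10-individual detection threshold; LOOCV is confirmed on one seed. These
sizes keep a full suite run to a few minutes while exercising every stage
at realistic dimensionality.

## Known limitations

- $\alpha$ is selected on the same grid it is evaluated on (no nested
  double cross-validation), matching common practice for clock
  construction; reported in-sample grid metrics are optimistic and the
  LOOCV confirmation is the honest estimate.
- The interarray outlier rule (mean correlation more than `z_cut` sd
  below the mean) is a reproducible stand-in for what is usually a visual
  dendrogram call; the dendrogram is retained in the report for review.
- Serialization stores doubles with `%.17g`; clocks round-trip
  bit-exactly through text, but files written by other software at lower
  precision will round-trip only to their own precision.
- The cross-validated penalty reported in `training_meta$penalty` follows
  the optimizer's native scale, while fixed-penalty solves interpret
  $\lambda$ exactly as in the objective above; the two coincide for the
  lasso but differ by a response-scale factor in the ridge component.
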