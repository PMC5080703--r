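---
title: "Estimating predictive performance on incomplete data: methods and design choices"
author: "valimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating predictive performance on incomplete data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valimpute)
```

## The problem

A prognostic study develops a classification model on an available data set
and wants to know how well that model will perform on *future* data. Apparent
performance — evaluating the model on the data used to fit it — is
optimistic, so internal validation (bootstrap, subsampling or
cross-validation) is used to correct for overfitting. When the development
data additionally contain missing covariate values, multiple imputation (MI)
is the standard remedy, but validation and imputation can be combined in
several orders, and the order matters: imputing the full data set first lets
information from future test observations leak into the imputed training
values. `valimpute` implements the competing combination strategies, the
optimism-correcting estimators, the performance measures, a simulation
engine with controlled effect sizes and missingness mechanisms, and
resampling-based confidence intervals, so that the strategies can be
compared against a known truth.

## Data-generating model

Outcomes are i.i.d. Bernoulli(`frac`). Covariates are multivariate normal
with unit variances and exchangeable correlation `rho` within each covariate
set; a common mean shift of `dmu / 2` is added to cases and subtracted from
controls. The shift is solved with `uniroot()` from the target "theoretical
AUC" through

\[ \mathrm{AUC} = \Phi\!\left(\tfrac12
   \sqrt{\Delta\mu^{T}\Sigma^{-1}\Delta\mu}\right), \]

with \(\Delta\mu = (\Delta\mu,\dots,\Delta\mu)\). This induces the logistic
model \(P(y=1\mid x) = \mathrm{logistic}(\gamma^{T}x)\) with
\(\gamma = \Sigma^{-1}\Delta\mu\). One property deserves emphasis: the
half-factor convention above is *not* the classical binormal identity
\(\mathrm{AUC} = \Phi(\delta/\sqrt2)\) with Mahalanobis distance
\(\delta\). A data set generated for nominal `auc` therefore attains the
population AUC \(\Phi(\sqrt2\,\Phi^{-1}(\mathrm{auc}))\) — e.g. 0.818 for
nominal 0.74. This is irrelevant for comparing estimation strategies (all
comparisons use a model-based truth, never the nominal grid value), but the
nominal parameter should be read as an effect-size *label*, not the attained
AUC; the test suite asserts the attained value explicitly. Under the null
(`auc = 0.5`) the two conventions coincide, so type-1-error experiments are
unaffected.

For *added* performance (situation 2), a baseline set of `p0` covariates is
solved to attain `auc0` on its own, and the additional set is then solved —
holding the baseline effect fixed and exploiting the block-diagonal
covariance — so the joint model attains `auc0 + dauc`.

## Missingness mechanisms

All mechanisms mask exactly `round(n * miss)` cells per covariate
(round-half-to-even), never the outcome:

* **MCAR** — cells uniformly at random, per covariate.
* **MAR** — covariate `j` is masked with probability
  `logistic(b0j + b1j * M[i, j-1] + b2j * X[i, kj] + 2 * y[i])`, where
  `M[i, j-1]` is the previous covariate's missingness indicator
  (`b1j = 0` for `j = 1`, otherwise ±1 with equal probability), `kj` is a
  randomly chosen other covariate (`b2j = 2` for `j > 1`, 0 for the first
  covariate, and the term is dropped entirely when `p = 1`), and the
  intercepts `b0j` are solved numerically so the mean probability equals
  `miss`.
* **MARblock** — covariates are randomly assigned to three blocks; within a
  block every covariate shares one partner covariate outside the block and
  is masked with probability `logistic(b0j + 10 * X[i, kb] + 2 * y[i])`,
  producing co-missingness of whole blocks as seen when laboratory panels
  are measured on subject subsets. Intercepts are re-solved per covariate
  after block assignment. At least two covariates are required.

Exact counts are achieved by weighted sampling of distinct cells without
replacement with weights proportional to the model probabilities; a
multinomial draw with replacement could select the same cell twice and
undershoot the target proportion. Probabilities are computed from the
complete (pre-masking) values, which are retained in the container for
truth-based evaluation only and never shown to estimation code.

## Imputation: chained equations with predictive mean matching

Before chaining, each incomplete variable is assigned the transformation
(raw, natural log, cubic root or square root; log/sqrt only on
positive/non-negative values) maximizing the Shapiro–Wilk statistic on its
*observed* values — once, not per sweep. For observed vectors longer than
5000 (the limit of `shapiro.test`), the statistic is computed on 5000 evenly
spaced order statistics, a deterministic reduction.

Each of the `M` imputations starts from a random fill of observed values and
performs `n_iterations = 5` sweeps (the conventional chained-equations
default) over the incomplete variables in order of increasing missingness.
Each sweep fits a Bayesian linear regression of the observed target values
on all other covariates (plus the outcome when `include_outcome = TRUE`):
the residual variance is drawn from a scaled inverse-\(\chi^2\), the
coefficients from their normal posterior, predictions are computed with the
posterior draw for missing rows and the least-squares estimate for observed
rows (type-1 matching), and each missing entry receives the observed value
of a donor drawn uniformly from the `n_donors = 5` observed rows with
closest predictions. Donors are located by a two-pointer scan over the
sorted predictions; exact prediction ties fall back to row order. A
numerically singular cross-product matrix falls back to a small ridge, with
a warning. Because donors are observed values, working on the transformed
scale is lossless: the inverse transformation is applied once on output and
observed cells are restored exactly.

Rubin's rules pool per-imputation estimates by their mean; when variances
are supplied the total variance is the mean within-imputation variance plus
\((1 + 1/M)\) times the between-imputation variance.

## Validation strategies and estimators

`draw_resamples()` provides bootstrap (`BS`, train drawn with replacement,
test = out-of-bag complement; empty out-of-bag sets are redrawn),
subsampling (`SS`, train = `round(0.632 n)` distinct observations) and
(repeated) K-fold cross-validation with fold sizes differing by at most one.
Stratification is deliberately not applied; degenerate single-class splits
are instead skipped and counted downstream (a hard error above 20%).

With \(\hat\theta^{A,B}\) the measure when fitting on A and evaluating on B,
the estimators are

* optimism-corrected: \(\hat\theta^{Orig,Orig} -
  (\hat\theta^{BS,BS} - \hat\theta^{BS,Orig})\);
* 0.632: \(0.368\,\hat\theta^{Orig,Orig} + 0.632\,\hat\theta^{OOB}\);
* 0.632+: \((1-w)\,\hat\theta^{Orig,Orig} + w\,\hat\theta^{OOB}\) with
  \(w = 0.632/(1 - 0.368 R)\) and relative overfitting rate
  \(R = (\hat\theta^{OOB} - \hat\theta^{Orig,Orig}) /
  (\hat\theta^{noinfo} - \hat\theta^{Orig,Orig})\).

`R` is clipped to \([0, 1]\) so that `w` stays in \([0.632, 1]\); the
clipping guard follows the original 0.632+ construction and also keeps the
algebra direction-agnostic (for the Brier score the no-information value
sits on the pessimistic side just as 0.5 does for AUC). The further
truncation of the out-of-bag value at the no-information value used by some
variants is *not* applied. The no-information performance is 0.5 for AUC, 0
for all added measures, and a 1000-permutation average of the measure under
permuted predictions otherwise (Brier, calibration). When the no-information
value coincides with the apparent value, `R` is defined as 0.

For cross-validation plans only the plain CV estimate (average test-fold
performance, per repetition and then across repetitions) is reported;
optimism correction applies to the bootstrap/subsampling geometry.

## Combining validation with imputation

* **Val-MI** — draw the B splits on the incomplete data; impute each
  training part and each test part separately, `M` times each, as
  self-contained data sets with their own outcome; pair train-imputation m
  with test-imputation m (B·M pairs, not B·M²). Apparent performance is the
  average fit-and-evaluate over `M` imputations of the full data (outcome
  included), and the same full-data copies serve as the "original" data for
  the optimism term \(\hat\theta^{BS,Orig}\), which is otherwise undefined
  on incomplete originals.
* **MI-Val / MI(-y)-Val** — impute the full data `M` times with / without
  the outcome in the imputation models, then draw B fresh splits per imputed
  copy and average across the B·M splits.
* **MI / MI(-y)** — Rubin-pooled apparent performance only, no validation.

Averages are taken across all (b, m) pairs first and the estimators applied
to the pooled averages. `Val-MI(-y)` is not offered: separate imputation of
training and test parts already keeps the test data blind to the training
outcome–covariate relationship.

On complete data every strategy collapses, bit-identically under a shared
seed, onto complete-data validation, because imputation of a complete data
set returns the input without consuming random numbers — a property the
tests assert and a useful guard against accidental RNG divergence. All
randomness in a strategy run flows from a single `set.seed` at entry with
documented phase order (plan, then imputations, then the permutation-based
no-information value when needed).

## Confidence intervals

The resampling interval collects
\(w_{b,m} = \hat\theta^{BS(b,m),BS(b,m)} - \hat\theta^{Orig,Orig}\), takes
the \(\alpha/2\) and \(1-\alpha/2\) empirical percentiles \(\xi\), and
reports \([\hat\theta^{0.632+} - \xi_{1-\alpha/2},\;
\hat\theta^{0.632+} - \xi_{\alpha/2}]\), i.e. the percentile interval of the
apparent error re-centred at the 0.632+ estimate. The recommended settings
are `B = 100, M = 1` for Val-MI and `M = 100, B = 1` for MI(-y)-Val; fewer
than 40 (b, m) values triggers a warning. Both interval bounds subtract a
percentile — the original percentile construction adds the lower one; the
re-centred form is implemented as specified for the 0.632+ context.

For apparent-only strategies the AUC (or its change) gets a DeLong
placement-value variance per imputed copy, pooled by Rubin's rules into a
normal-approximation interval. On complete data this reduces to the plain
DeLong interval; the implementation is rank-based and is cross-checked in
the tests against a brute-force placement oracle and against `pROC`.

## Evaluation design

"True" performance of a setting is the average measure of models fitted on
fresh complete data sets of size `n` and evaluated on large independent
complete data sets (default `n_test = 10000`), which is below the attained
population AUC in small samples. Bias, variance and MSE of strategy
estimates are taken against this truth. The type-1-error experiment counts
intervals lying entirely above the null value (0.5 for AUC, 0 for added
measures); the variability experiment re-runs a strategy with fresh
resampling/imputation randomness and checks the \(1/\sqrt{B}\) scaling of
the SD of the 0.632+ estimate expected from independent bootstrap
contributions (and the analogous role of `M` for imputation-first
strategies). The future-data experiment fits on complete data and evaluates
on large independent test sets carrying increasing MCAR missingness,
imputed without the outcome using the test set alone as the imputation
basis — mimicking application-stage data availability, where no outcome and
no development data are at hand.

## Problem sizes and defaults

Defaults follow the simulation-scale choices: `B = 10` resamples with
`M = 5` imputations for estimation, `B = 100, M = 1` (Val-MI) or
`B = 1, M = 100` (MI(-y)-Val) for confidence intervals, 250 replicates for
full bias studies (`n_replicates` arguments allow desk-scale runs; the test
suite uses 100 replicates for ordering assertions, 200 simulated data sets
for the type-1-error check, and reduced Monte-Carlo sizes elsewhere, chosen
so the whole suite runs in minutes on one core).

## What the generator does and does not emulate

The synthetic data are multivariate normal with exchangeable within-set
correlation, a single common effect size per covariate set, and logistic
missingness models with fixed coefficient magnitudes (±1 on neighbour
missingness, 2 on a partner covariate, 2 on the outcome, 10 on a block
partner). Real epidemiological data feature skewed and categorical
covariates, heterogeneous effects, and missingness patterns tied to study
design; passing tests on the generator therefore demonstrate correctness of
the estimation machinery and the qualitative strategy orderings, not
transferability of any particular bias magnitude to a given real data set.
Categorical imputation models, survival outcomes and time-dependent AUC,
real-data missingness-pattern mimicking, and penalized/high-dimensional
models with selection are out of scope.

## Known limitations

* Calibration measures use `logit(p_hat)` as the regression covariate (the
  standard calibration-slope convention) with probabilities clipped to
  `[1e-12, 1 - 1e-12]`; perfectly separated fits are flagged, not repaired.
* The categorical NRI uses per-class proportions (Pencina convention) with
  the three categories `[0, frac/2]`, `(frac/2, 3 frac/2]`, `(3 frac/2, 1]`;
  boundary values fall into the lower category.
* Degenerate bootstrap draws, empty donor pools and near-singular imputation
  models are handled by redraw, error and ridge fallback respectively; the
  contracts are total but the statistical behaviour in such corners is not
  studied.
* `MI-Val` draws fresh splits per imputed copy; sharing one plan across
  copies would slightly reduce variance but is not what the combination
  scheme prescribes.
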