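---
title: "Imputing limited-range variables: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing limited-range variables: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangemi)
```

`rangemi` studies a narrow but consequential question in missing-data
practice: when a bounded score is multiply imputed from a conditionally
normal model, should imputations that fall outside the possible range be
"repaired"? The package implements four univariate imputation methods, a
missingness-resampling evaluation design, and a synthetic data generator
that reproduces the score distributions the question hinges on. This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, so that results can be interpreted —
and distrusted — for the right reasons.

## The evaluation design

A single complete dataset is treated as the population of interest. Its
complete-data statistics — here the marginal mean of the score, and the
slope from a univariable logistic regression of a fully observed binary
outcome on the score — are the estimands, denoted $\hat Q$ with
complete-data variance $U$. Each of $N$ replicates deletes a fraction of
the scores, imputes them $m$ times, analyses each completed copy, and
pools with Rubin's rules: the pooled estimate $\bar Q_m$, the
within-imputation variance $\bar U_m$ (mean of the squared per-copy
standard errors), and the between-imputation variance $B_m$ (unbiased
variance of the per-copy estimates).

Four properties are reported per method:

* **bias** $E[\bar Q_m] - \hat Q$, averaging over replicates;
* **within-variance calibration**: $E[\bar U_m]$ should equal $U$;
* **between-variance calibration**: the empirical $\mathrm{Var}(\bar Q_m)$
  across replicates should equal $(1 + 1/m)\,E[B_m]$;
* **coverage**: the fraction of replicates in which
  $\bar Q_m \mp t_{m-1,0.975}\sqrt{(1 + 1/m)B_m}$ contains $\hat Q$
  (closed interval).

The interval deliberately uses only the between-imputation component.
Because $\hat Q$ is held fixed and only the missingness is redrawn, the
sampling variability of $\bar Q_m$ around $\hat Q$ is exactly the
missing-information component that $(1+1/m)B_m$ estimates; adding
$\bar U_m$ would target the population parameter instead and would push
coverage of $\hat Q$ to 1 regardless of the imputation method, hiding the
differences the design exists to expose. `rubin_pool()` defaults to this
`"between"` interval with $t_{m-1}$ degrees of freedom; the classical
total-variance interval (and the Rubin large-sample degrees of freedom)
remain available via its `interval` and `df` arguments for ordinary MI
analyses.

Out-of-range accounting is reported for the linear-regression methods: the
average percentage of imputed values below and above the limits, counted
on the imputation scale *before* any clamping.

## The synthetic data generator

The generator emulates a 12-item psychological-distress questionnaire
(GHQ-12-like) measured on two waves, plus a binary outcome. It exists
because the three scoring rules of such an instrument span exactly the
skewness regimes of interest on hard-bounded ranges:

* **Likert scoring** (items 0-1-2-3, total 0–36): mild positive skew;
* **C-GHQ scoring** (0-0-1-1 on positively worded, 0-1-1-1 on negatively
  worded items, total 0–12): moderate positive skew;
* **standard scoring** (0-0-1-1, total 0–12): severe positive skew with a
  point mass at zero.

Items follow a single-factor ordinal probit model: person latent
$L_i \sim N(0,1)$; item $j$'s response is the number of its three
increasing cutpoints lying below $L_i + \sigma_e e_{ij}$,
$e_{ij} \sim N(0,1)$. Six of the twelve items are flagged negatively
worded (positions 2, 5, 6, 9, 10, 11, the conventional GHQ-12 layout);
the flags matter only to C-GHQ scoring and are configurable — which items
of the real instrument are negatively worded is not modelled, only the
6/6 split.

Cutpoints and noise were calibrated once, by Monte-Carlo search at
$n = 2\times 10^5$, to land inside the target regimes, and then frozen:

| profile | cutpoints (per item offsets of ±0.25 spread) | noise SD | large-sample result |
|---|---|---|---|
| `likert_like` | (−0.3, 1.0, 2.3) | 1.0 | Likert skewness ≈ 0.64 |
| `cghq_like` | (0.7, 1.7, 2.6) | 1.0 | C-GHQ skewness ≈ 1.18 |
| `standard_like` | second cutpoints (−0.25, −0.05, 1.5 … 3.0); first/third ∓0.9 | 0.8 | skewness ≈ 1.8, zero mass ≈ 0.30 |

The severe profile needs heterogeneous item difficulties — two "easy"
items plus ten hard ones — because with a Gaussian person latent a
uniform-difficulty item set cannot combine a 0.30 zero mass with score
skewness above 1.5: lowering difficulties to thin the zero class fills in
the low scores and destroys the skew.

The wave-9 auxiliary is built honestly from the same machinery: a second
person latent correlated at `latent_correlation` (default 0.5) with the
wave-8 latent generates a fresh item table with the mild-skew thresholds,
which is Likert-scored and binned at 0–5 / 6–8 / 9–11 / 12–36 into four
severity categories. The binary outcome is Bernoulli with
$\mathrm{logit}^{-1}(-0.6 + 0.4\,L_i)$ — a prevalence near one third with
a modest positive association with distress; both link parameters are
profile fields.

What the generator does **not** emulate: the marginal distributions of any
real cohort (only the skew regimes), sampling variability of the complete
dataset (the design conditions on one draw), item-level missingness,
measurement error structure beyond the single factor, and any demographic
restriction. Passing tests therefore show that the *methods* behave as
theory predicts under these skew regimes — not that any numeric cell would
reproduce on a particular real dataset.

Default sample size is $n = 714$.

## Missingness

`missingness_spec()` fixes the mechanism and its parameters; the defaults
delete one third of the scores.

* **MCAR** deletes exactly `round(prop * n)` scores by simple random
  sampling. A fixed count was chosen over per-unit Bernoulli draws to
  remove one source of pure simulation noise; the choice is configurable
  in effect, since the MAR machinery accepts zero slopes.
* **MAR** deletes score $i$ with probability
  $\mathrm{logit}^{-1}(\alpha + 1.25\,D_i + 0.2\,[A_i{=}\text{mod}] +
  0.3\,[A_i{=}\text{high}] + 0.4\,[A_i{=}\text{vhigh}])$ — odds ratios
  3.5, 1.22, 1.35, 1.5. The intercept is calibrated by `calibrate_alpha()`
  so the *mean* probability over the fixed complete dataset equals the
  target (monotone root-finding; tolerance $10^{-6}$ on the mean). The
  calibration happens once per dataset, not per replicate: the
  specification is part of the scenario, and per-replicate recalibration
  would shrink the realized-proportion variance the mechanism is supposed
  to have.

Only the score is ever deleted; outcome and auxiliary stay complete.

## The zero-skewness transform

`fit_zero_skew()` finds the shift $k < \min(x)$ making the moment
skewness coefficient $g_1 = m_3/m_2^{3/2}$ of $\ln(x - k)$ zero, by
bracketing root search on a log-reparametrised shift (achieved $|g_1| <
10^{-6}$ is asserted). $g_1$ is the conventional zero-skewness criterion;
nothing in the results is sensitive to the small-sample bias correction.
Range limits map to $\ln(lo - k)$ and $\ln(hi - k)$; since $k$ must fall
below the smallest observation, a point mass at the lower limit needs no
ad hoc offset. The transform is fitted on the *observed* values within
each replicate — what an analyst holding incomplete data can actually do —
rather than once on the complete data; the alternative is one function
call away but is not the default. Back-transformation is exact and never
clips: wildly large back-transformed imputations on a severely skewed
score are a finding, not a bug, and the pipeline must surface them.

## The four imputers

All methods share the design matrix: intercept, binary outcome, and three
auxiliary indicators (low as reference). Indicators rather than a linear
auxiliary score were chosen to match how the missingness model itself uses
the variable. Each of the $m$ copies uses a fresh parameter draw — proper
imputation — so $B_m$ reflects parameter uncertainty.

**Linear regression, non-rounded** (`regress`): the standard Bayesian
draw under the noninformative prior, $\sigma^{*2} = \mathrm{RSS}/
\chi^2_{n_{obs}-p}$, $\beta^* \sim N(\hat\beta, \sigma^{*2}(X'X)^{-1})$,
then $y_i^* = x_i'\beta^* + \sigma^* z_i$. Out-of-range values are kept.
A zero residual sum of squares is an error, never silently imputed.

**Post-imputation rounding** (`regress_round`): identical draws, then
imputed entries are clamped to the limits. Counts of out-of-range values
are recorded before clamping.

**Truncated normal regression** (`truncreg`): ML fit of the
normal-density-renormalised-to-$(lo,hi)$ regression, optimised over
$(\beta, \ln\sigma)$ by BFGS with analytic gradients from a least-squares
start; per-copy parameters drawn from the asymptotic normal approximation
at the optimum (inverse observed information); imputations by inverse-CDF
sampling of the truncated normal, computed in log tail probabilities so
the sampler survives parameter draws that put nearly all parent mass
outside the bounds. Two behaviours deserve emphasis:

* *The truncation interval is open.* Observations lying exactly on a bound
  are regarded as truncated out of the estimation sample, the semantics of
  standard truncated-regression tools (a continuous open-interval density
  gives them zero likelihood). For a zero-inflated score this is the
  mechanism of the method's failure: a ~30% point mass at the floor simply
  never informs the fit, which then reproduces the distribution of the
  *interior* values — biasing the marginal mean upward with a confidently
  small between-imputation variance, hence drastic under-coverage. If the
  boundary observations are instead included in the likelihood, the model
  is so badly misspecified that the fit escapes along a degenerate ridge
  towards a truncated-exponential limit, with runaway parameters and
  exploding draw variance — numerically survivable but not what any
  practitioner's tool does.
* *Convergence is declared on the objective.* BFGS restart sweeps continue
  until the gradient vanishes or the log-likelihood stops improving by
  more than $10^{-7}$; on near-degenerate fits the predictive distribution
  stabilises long before the parameters do. Fits whose Hessian is not
  usable (non-finite or non-positive-definite inverse) are flagged as
  failed; the simulation engine records and excludes such replicates per
  method rather than substituting another imputer.

**Predictive mean matching** (`pmm`, $k = 5$): type-1 matching — predicted
means for missing cases use the fresh draw $\beta^*$, donor predictions
use $\hat\beta$ — with donors the $k$ observed cases nearest in predicted
mean, ties broken by position after a seeded shuffle, and the imputed
value copied from a uniformly chosen donor. Type-0 matching (both
predictions from $\beta^*$) is available via `matching = "type0"`. The
exact donor and tie rules of other implementations are not claimed; the
rule here is simply stated and tested against a transcription oracle.
Donor values are observed values, so PMM never leaves the range.

## The simulation engine

`scenario_config()` + `run_scenario()` wire the above together. Per-
replicate seeds form a logged substream drawn from the master seed, so a
full rerun is identical cell for cell and any single replicate can be
rerun in isolation (`run_replicate()`). Failed replicates are excluded
per-method with counts in the report; a method failing in every replicate
yields an `NA` row rather than an error.

Problem sizes used by the package's own test and acceptance runs: the
coverage properties are computed at $N = 1000$ replicates, $n = 714$,
$m = 20$ (the Monte-Carlo standard error of a 0.95 coverage proportion at
$N = 1000$ is about 0.007); the directional comparisons (bias orderings,
out-of-range asymmetry, robustness of the association estimate) use
$N = 200$, which is ample for orderings whose effects are tens of
Monte-Carlo standard errors wide.

## Numerical choices, degenerate inputs, limitations

* Tolerances: zero-skewness $|g_1| < 10^{-6}$; MAR calibration $10^{-6}$
  on the mean probability; logistic Newton–Raphson $10^{-8}$ on the slope
  update; truncated-regression gradient target $10^{-4}$ with the
  objective-stagnation fallback described above.
* Degenerate inputs error early and loudly: constant scores, zero RSS,
  rank-deficient designs, single-class outcomes, non-positive skewness
  handed to the transform, $k$ exceeding the donor pool.
* Scores are analysed as continuous; "rounding" in this package always
  means clamping to the range limits, never rounding to integers.
* The evaluation conditions on one synthetic complete dataset per
  scenario; conclusions are about imputation-method behaviour under these
  skew regimes, and transfer to other datasets only in direction, not in
  magnitude. Multivariate missingness patterns, chained equations, MNAR
  mechanisms and ordinal-logistic imputation are out of scope by design.
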