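# rangemi

Multiple imputation (MI) for **limited-range variables**: bounded, often
positively skewed scores such as questionnaire totals. When such a score is
imputed from a normal linear model, some imputations fall outside the
possible range, and analysts routinely "fix" this — by clamping imputed
values to the limits, by imputing from a truncated normal model, or by
predictive mean matching. `rangemi` provides the machinery to study what
those fixes do to inference: a synthetic General Health Questionnaire
(GHQ-12)-like data generator, MCAR/MAR missingness mechanisms, the four
univariate imputers, a zero-skewness log transform, Rubin's-rules pooling,
and a missingness-resampling simulation engine.

The headline finding this machinery reproduces: *restricting the range of
imputed values is what biases the marginal mean*. Plain regression
imputation with out-of-range values left alone is essentially unbiased and
attains nominal coverage even under severe skew, while post-imputation
rounding and truncated-normal imputation inflate the mean and under-cover —
drastically so for a zero-inflated score.

## The design

One complete dataset of `n` subjects is held fixed: a bounded score
`Y ∈ [lo, hi]`, a binary outcome `D`, and a 4-level ordinal auxiliary `A`.
Complete-data statistics `Q̂` (marginal mean of `Y`, or the logistic slope
of `D` on `Y`) and their variance `U` are computed once. Then, `N` times:

1. delete ~33% of the scores — MCAR (simple random sample) or MAR via
   `logit P(missing) = α + 1.25·D + 0.2·A_mod + 0.3·A_high + 0.4·A_vhigh`,
   with `α` calibrated so the mean probability equals the target;
2. impute `m = 20` times with each method (imputation model: intercept,
   outcome, three auxiliary indicators), on the raw or zero-skewness
   log-transformed scale;
3. analyse each completed copy and pool: `Q̄m` (mean estimate), `Ūm`
   (within-imputation variance), `Bm` (between-imputation variance).

Performance over the `N` replicates: bias `E[Q̄m] − Q̂`, the variance
calibration pair `Var(Q̄m)` vs `(1 + 1/m)·E[Bm]`, coverage of the nominal
95% intervals `Q̄m ∓ t_{m−1,0.975}·√((1 + 1/m)·Bm)` (under this design `Q̂`
is fixed, so only the between component reflects the sampling variability
of `Q̄m`), and the average percentage of values imputed outside `[lo, hi]`.

## Worked example

```r
library(rangemi)

d <- make_dataset(n = 714, profile = "standard_like", seed = 1)
d
#> complete_dataset: n = 714  score range [ 0 , 12 ]
#>   profile: standard_like  scoring: standard
#>   score mean 1.542  skewness 1.803
#>   outcome prevalence 0.346  aux: low=211 moderate=116 high=90 very_high=297

cfg <- scenario_config("standard_like", mechanism = "MCAR", N = 200, m = 20,
                       methods = c("regress", "regress_round", "truncreg", "pmm"),
                       scales = "raw", parameters = "marginal_mean", seed = 1)
run_scenario(cfg)
#> Missingness-resampling performance report (MCAR, N = 200, m = 20)
#>   marginal_mean: Q-hat = 1.54202  U = 0.004018
#>      parameter        method scale e_q_bar    bias e_u_bar var_q_bar
#>  marginal_mean       regress   raw  1.5362 -0.0058  0.0040    0.0021
#>  marginal_mean regress_round   raw  1.5927  0.0507  0.0037    0.0021
#>  marginal_mean      truncreg   raw  1.7506  0.2086  0.0039    0.0020
#>  marginal_mean           pmm   raw  1.5384 -0.0036  0.0040    0.0026
#>  between_est coverage pct_below pct_above n_failed
#>       0.0018    0.925   18.4831         0        0
#>       0.0014    0.735   18.4606         0        0
#>       0.0019    0.000    0.0000         0        0
#>       0.0145    1.000    0.0000         0        0
```

Reading the rows: the severely skewed score (zero mass ≈ 0.30, skewness
1.8) is imputed essentially without bias by plain regression even though
18% of its imputations land below zero, and its intervals cover the
complete-data mean at close to the nominal rate. Clamping those values to
the floor (`regress_round`) shifts the mean up by 0.05 and drops coverage
to 0.74. Truncated-normal regression — whose fit can only see the scores
strictly inside the bounds, so the zero point mass never informs it —
overshoots the mean by 0.21 and covers 0% of the time. PMM is nearly
unbiased here but over-states the between-imputation variance.

Lower-level pieces are exposed individually: `impose_missingness()`,
`calibrate_alpha()`, `multiple_impute()`, `fit_zero_skew()`,
`fit_truncreg()`, `rtruncnorm_inv()`, `rubin_pool()`, and so on; see the
help pages and `vignettes/limited-range-imputation.Rmd`.

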