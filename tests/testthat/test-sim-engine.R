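test_that("a vanishing missingness proportion gives zero bias and full coverage", {
  cfg <- scenario_config("likert_like", mechanism = "MCAR", N = 2, m = 2,
                         methods = "regress", scales = "raw",
                         parameters = "marginal_mean", prop = 1e-4,
                         n = 200, seed = 81)
  rep <- run_scenario(cfg)  # round(1e-4 * 200) = 0 scores deleted
  expect_equal(rep$bias, 0)
  expect_equal(rep$coverage, 1)
})

test_that("a scenario rerun with the same master seed is reproducible cell for cell", {
  cfg <- scenario_config("standard_like", mechanism = "MAR", N = 8, m = 4,
                         methods = c("regress", "pmm"), scales = "raw",
                         parameters = "marginal_mean", n = 200, seed = 82)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1, r2)
  # and a single replicate reruns exactly in isolation
  data <- make_dataset(200, "standard_like", seed = 82)
  spec <- calibrate_alpha(data, missingness_spec("MAR"))
  seeds <- attr(r1, "rep_seeds")
  a <- run_replicate(data, spec, cfg, seeds[5])
  b <- run_replicate(data, spec, cfg, seeds[5])
  expect_identical(a, b)
  expect_false(identical(a, run_replicate(data, spec, cfg, seeds[6])))
})

test_that("variance summaries equal their brute-force counterparts", {
  set.seed(83)
  qb <- stats::rnorm(50, 3); ub <- stats::rchisq(50, 2); bm <- stats::rchisq(50, 1)
  vc <- mi_variance_checks(qb, ub, bm, m = 20)
  expect_equal(vc[["e_u_bar"]], sum(ub) / 50)
  expect_equal(vc[["between_est"]], (1 + 1 / 20) * sum(bm) / 50)
  expect_equal(vc[["var_q_bar"]], sum((qb - mean(qb))^2) / 49)
})

test_that("coverage agrees with a direct transcription of the interval formula", {
  set.seed(84)
  m <- 20
  pooled <- lapply(1:100, function(i)
    rubin_pool(estimates = stats::rnorm(m, 5, 0.3),
               variances = stats::rchisq(m, 3) / 30))
  q_hat <- 5.1
  got <- mi_coverage(pooled, q_hat)
  tq <- stats::qt(0.975, m - 1)
  manual <- vapply(pooled, function(p) {
    half <- tq * sqrt((1 + 1 / m) * p$b_m)
    p$q_bar - half <= q_hat && q_hat <= p$q_bar + half
  }, logical(1))
  expect_equal(got, mean(manual))
  expect_identical(vapply(pooled, function(p)
    p$ci_lo <= q_hat && q_hat <= p$ci_hi, logical(1)), manual)
})

test_that("out-of-range percentages equal a recount from the stored copies", {
  d <- make_dataset(714, "standard_like", seed = 85)
  spec <- missingness_spec("MCAR")
  sets <- lapply(1:4, function(s) {
    inc <- set_missing(d, impose_missingness(d, spec, s))
    multiple_impute(inc, "regress", m = 5, seed = 100 + s)
  })
  got <- pct_out_of_range(sets)
  recount <- sapply(sets, function(cs) {
    imp <- cs$imputations[cs$mask, ]
    c(100 * mean(colSums(imp < cs$lo) / cs$n_missing),
      100 * mean(colSums(imp > cs$hi) / cs$n_missing))
  })
  expect_equal(unname(got), rowMeans(recount))
  expect_gt(got[["pct_below"]], got[["pct_above"]])
})

test_that("failed replicates are counted and excluded rather than imputed", {
  # a dataset whose interior support is too thin for truncated regression:
  # all scores sit on the bounds, so every truncreg replicate must fail
  set.seed(86)
  score <- rep(c(0, 12), each = 30)
  outcome <- stats::rbinom(60, 1, 0.5)
  aux <- factor(sample(c("low", "moderate", "high", "very_high"), 60, TRUE),
                levels = c("low", "moderate", "high", "very_high"),
                ordered = TRUE)
  d <- complete_dataset(score, 0, 12, outcome, aux)
  cfg <- scenario_config(mechanism = "MCAR", N = 3, m = 3,
                         methods = c("regress", "truncreg"), scales = "raw",
                         parameters = "marginal_mean", n = 60, seed = 87)
  rep <- run_scenario(cfg, data = d)
  tr <- rep[rep$method == "truncreg", ]
  expect_equal(tr$n_failed, 3)
  expect_true(is.na(tr$e_q_bar))
  expect_equal(rep[rep$method == "regress", "n_failed"], 0)
})
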