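test_that("scoring rules agree with brute-force enumeration of single-item patterns", {
  neg <- rep(FALSE, 12); neg[c(2, 5, 6, 9, 10, 11)] <- TRUE
  rows <- list(); expected <- list()
  for (j in 1:12) for (v in 0:3) {
    r <- integer(12); r[j] <- v
    rows[[length(rows) + 1]] <- r
    expected[[length(expected) + 1]] <- c(
      likert = v,
      standard = as.integer(v >= 2),
      cghq = if (neg[j]) as.integer(v >= 1) else as.integer(v >= 2))
  }
  items <- do.call(rbind, rows)
  exp_mat <- do.call(rbind, expected)
  expect_equal(score_items(items, "likert", neg), unname(exp_mat[, "likert"]))
  expect_equal(score_items(items, "standard", neg), unname(exp_mat[, "standard"]))
  expect_equal(score_items(items, "cghq", neg), unname(exp_mat[, "cghq"]))

  all3 <- matrix(3L, 1, 12); all0 <- matrix(0L, 1, 12)
  expect_equal(score_items(all3, "likert", neg), 36)
  expect_equal(score_items(all3, "standard", neg), 12)
  expect_equal(score_items(all3, "cghq", neg), 12)
  expect_equal(score_items(all0, "likert", neg), 0)
  expect_equal(score_items(all0, "standard", neg), 0)
  expect_equal(score_items(all0, "cghq", neg), 0)
})

test_that("degenerate cutpoints pin all responses to the floor or ceiling", {
  pr_hi <- synth_profile("likert_like",
                         item_thresholds = matrix(Inf, 12, 3))
  expect_true(all(generate_items(50, pr_hi, 1)$responses == 0))
  pr_lo <- synth_profile("likert_like",
                         item_thresholds = matrix(-Inf, 12, 3))
  expect_true(all(generate_items(50, pr_lo, 1)$responses == 3))
})

test_that("non-increasing finite cutpoints are rejected", {
  bad <- cbind(rep(1, 12), rep(0.5, 12), rep(2, 12))
  expect_error(synth_profile("likert_like", item_thresholds = bad),
               "increasing")
})

test_that("datasets are reproducible given a seed and respect their bounds", {
  d1 <- make_dataset(714, "likert_like", seed = 3)
  d2 <- make_dataset(714, "likert_like", seed = 3)
  expect_identical(d1, d2)
  d3 <- make_dataset(714, "likert_like", seed = 4)
  expect_false(identical(d1$score, d3$score))
  expect_true(all(d1$score >= 0 & d1$score <= 36))
  expect_false(anyNA(d1$score))
  ds <- make_dataset(714, "standard_like", seed = 3)
  expect_true(all(ds$score >= 0 & ds$score <= 12))
})

test_that("profiles reproduce the mild / moderate / severe skew regimes", {
  n <- 1e5
  lik <- make_dataset(n, "likert_like", seed = 21)
  cg <- make_dataset(n, "cghq_like", seed = 22)
  std <- make_dataset(n, "standard_like", seed = 23)
  sk_lik <- sample_skewness(lik$score)
  sk_cg <- sample_skewness(cg$score)
  sk_std <- sample_skewness(std$score)
  expect_gt(sk_lik, 0.2); expect_lt(sk_lik, 0.8)
  expect_gt(sk_cg, 0.8); expect_lt(sk_cg, 1.5)
  expect_gt(sk_std, 1.5)
  expect_lt(sk_lik, sk_cg)
  expect_lt(sk_cg, sk_std)
  # point mass at zero for the severe profile
  expect_lt(abs(mean(std$score == 0) - 0.30), 0.05)
})

test_that("auxiliary is correlated with the score and outcome follows its link", {
  d <- make_dataset(5e4, "likert_like", seed = 31)
  expect_gt(stats::cor(d$score, as.integer(d$aux), method = "spearman"), 0.2)
  # null-association outcome: prevalence matches the intercept link
  pr0 <- synth_profile("likert_like", outcome_slope = 0,
                       outcome_intercept = -0.6)
  items <- generate_items(5e4, pr0, 32)
  ao <- generate_aux_outcome(items$latent, pr0, 33)
  p_target <- stats::plogis(-0.6)
  mc_se <- sqrt(p_target * (1 - p_target) / 5e4)
  expect_lt(abs(mean(ao$outcome) - p_target), 3 * mc_se)
  expect_true(all(levels(ao$aux) == c("low", "moderate", "high", "very_high")))
})
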