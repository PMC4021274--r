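#' Built-in synthetic GHQ profiles
#'
#' A profile bundles the parameters of the latent-variable item model used to
#' generate synthetic 12-item GHQ-like questionnaire data: per-item cutpoints
#' on the latent scale, the item noise standard deviation, the correlation
#' between the two waves' person latents, the logistic link for the binary
#' outcome, and (for the severe profile) the targeted point mass at zero.
#'
#' Three profiles are built in, named for the scoring rule whose skew regime
#' they were calibrated to reproduce on large samples:
#' \describe{
#'   \item{\code{likert_like}}{Likert score (0--36) with mild positive skew
#'     (about 0.6).}
#'   \item{\code{cghq_like}}{C-GHQ score (0--12) with moderate positive skew
#'     (about 1.2).}
#'   \item{\code{standard_like}}{standard score (0--12) with severe positive
#'     skew (about 1.8) and a point mass at zero of about 0.30.}
#' }
#'
#' Items use a single-factor ordinal probit model: person latent
#' \eqn{L_i \sim N(0,1)}, item response \eqn{x_{ij}} = number of cutpoints of
#' item \eqn{j} lying below \eqn{L_i + \sigma_e e_{ij}} with standard-normal
#' noise \eqn{e_{ij}}. Six of the twelve items are flagged as negatively
#' worded (positions 2, 5, 6, 9, 10 and 11, the conventional GHQ-12 layout);
#' the flags only matter to the C-GHQ scoring rule and are configurable.
#'
#' @param name one of \code{"likert_like"}, \code{"cghq_like"},
#'   \code{"standard_like"}.
#' @param item_thresholds optional 12 x 3 matrix of increasing cutpoints per
#'   item, overriding the calibrated defaults.
#' @param noise_sd item noise standard deviation.
#' @param latent_correlation correlation in (0,1) between the wave-8 person
#'   latent and the wave-9 latent used for the auxiliary variable.
#' @param outcome_intercept,outcome_slope logistic-link parameters for the
#'   binary outcome given the wave-8 person latent.
#' @param zero_mass_target targeted share of zero scores (standard scoring,
#'   severe profile).
#' @param negative_items logical vector of length 12 flagging negatively
#'   worded items.
#' @return an object of class \code{synth_profile}.
#' @examples
#' p <- synth_profile("standard_like")
#' p$zero_mass_target
#' @export
synth_profile <- function(name = c("likert_like", "cghq_like", "standard_like"),
                          item_thresholds = NULL,
                          noise_sd = NULL,
                          latent_correlation = 0.5,
                          outcome_intercept = -0.6,
                          outcome_slope = 0.4,
                          zero_mass_target = 0.30,
                          negative_items = NULL) {
  name <- match.arg(name)
  offsets <- seq(-0.25, 0.25, length.out = 12)
  if (is.null(item_thresholds)) {
    item_thresholds <- switch(name,
      likert_like = cbind(-0.3 + offsets, 1.0 + offsets, 2.3 + offsets),
      cghq_like   = cbind(0.7 + offsets, 1.7 + offsets, 2.6 + offsets),
      standard_like = {
        c2 <- c(-0.25, -0.05, seq(1.5, 3.0, length.out = 10))
        cbind(c2 - 0.9, c2, c2 + 0.9)
      })
  }
  item_thresholds <- as.matrix(item_thresholds)
  if (!identical(dim(item_thresholds), c(12L, 3L)))
    stop("item_thresholds must be a 12 x 3 matrix")
  validate_thresholds(item_thresholds)
  if (is.null(noise_sd))
    noise_sd <- if (name == "standard_like") 0.8 else 1.0
  if (is.null(negative_items)) {
    negative_items <- rep(FALSE, 12)
    negative_items[c(2, 5, 6, 9, 10, 11)] <- TRUE
  }
  if (length(negative_items) != 12 || !any(negative_items) || all(negative_items))
    stop("negative_items must flag at least one and not all of the 12 items")
  if (!(latent_correlation > 0 && latent_correlation < 1) &&
      latent_correlation != 1)  # rho = 1 allowed for degenerate checks
    stop("latent_correlation must lie in (0, 1]")
  if (zero_mass_target < 0 || zero_mass_target >= 1)
    stop("zero_mass_target must lie in [0, 1)")
  structure(list(name = name,
                 item_thresholds = item_thresholds,
                 noise_sd = noise_sd,
                 latent_correlation = latent_correlation,
                 outcome_intercept = outcome_intercept,
                 outcome_slope = outcome_slope,
                 zero_mass_target = zero_mass_target,
                 negative_items = as.logical(negative_items)),
            class = "synth_profile")
}

# cutpoints must be non-decreasing, strictly so where finite (infinite
# cutpoints may tie, which turns response levels off entirely)
validate_thresholds <- function(th) {
  for (j in seq_len(nrow(th))) {
    d <- diff(th[j, ])
    bad <- !is.na(d) & (d < 0 | (d == 0 & is.finite(th[j, -1])))
    # NaN differences arise only from equal infinite cutpoints, which are
    # allowed (they switch response levels off)
    if (any(bad)) stop("item_thresholds must be increasing within each item")
  }
  invisible(th)
}

#' @export
print.synth_profile <- function(x, ...) {
  cat("Synthetic GHQ profile:", x$name, "\n")
  cat("  item noise SD:", x$noise_sd,
      " latent correlation:", x$latent_correlation, "\n")
  cat("  outcome link: expit(", x$outcome_intercept, " + ",
      x$outcome_slope, " * latent )\n", sep = "")
  if (x$name == "standard_like")
    cat("  zero-mass target:", x$zero_mass_target, "\n")
  invisible(x)
}

#' Generate a synthetic 12-item response table
#'
#' Draws \code{n} response vectors from the profile's single-factor ordinal
#' model: one standard-normal person latent per row, and item response equal
#' to the count of that item's cutpoints lying below latent plus noise.
#'
#' @param n number of respondents.
#' @param profile a [synth_profile()].
#' @param seed integer seed; the result is reproducible given the seed.
#' @return an object of class \code{ghq_items}: a list with \code{responses}
#'   (n x 12 integer matrix with entries in 0..3), \code{negative_items},
#'   and the person \code{latent} used (needed downstream for the correlated
#'   auxiliary variable and outcome).
#' @export
generate_items <- function(n, profile, seed) {
  stopifnot(inherits(profile, "synth_profile"), n >= 1)
  set.seed(seed)
  latent <- stats::rnorm(n)
  items <- items_from_latent(latent, profile)
  structure(list(responses = items,
                 negative_items = profile$negative_items,
                 latent = latent),
            class = "ghq_items")
}

items_from_latent <- function(latent, profile) {
  n <- length(latent)
  th <- profile$item_thresholds
  z <- latent + profile$noise_sd * matrix(stats::rnorm(n * 12), n, 12)
  items <- matrix(0L, n, 12)
  for (j in 1:12)
    items[, j] <- (z[, j] > th[j, 1]) + (z[, j] > th[j, 2]) + (z[, j] > th[j, 3])
  items
}

#' @export
print.ghq_items <- function(x, ...) {
  cat("ghq_items:", nrow(x$responses), "respondents x 12 items;",
      sum(x$negative_items), "negatively worded\n")
  invisible(x)
}

#' Score a 12-item response table
#'
#' The three GHQ scoring rules:
#' \describe{
#'   \item{\code{likert}}{item pattern 0-1-2-3, total range 0--36.}
#'   \item{\code{standard}}{item pattern 0-0-1-1, total range 0--12.}
#'   \item{\code{cghq}}{0-0-1-1 for positively worded items, 0-1-1-1 for
#'     negatively worded items, total range 0--12.}
#' }
#'
#' @param items a \code{ghq_items} object (or a plain n x 12 matrix of codes
#'   in 0..3, in which case \code{negative_items} must be supplied).
#' @param method scoring rule.
#' @param negative_items logical flags, only used when \code{items} is a bare
#'   matrix.
#' @return numeric score vector.
#' @export
score_items <- function(items, method = c("likert", "standard", "cghq"),
                        negative_items = NULL) {
  method <- match.arg(method)
  if (inherits(items, "ghq_items")) {
    negative_items <- items$negative_items
    items <- items$responses
  }
  items <- as.matrix(items)
  if (ncol(items) != 12) stop("expected 12 item columns")
  if (!all(items %in% 0:3)) stop("item codes must be in {0,1,2,3}")
  switch(method,
    likert = rowSums(items),
    standard = rowSums(items >= 2),
    cghq = {
      if (is.null(negative_items)) stop("cghq scoring needs negative_items flags")
      rowSums(items[, !negative_items, drop = FALSE] >= 2) +
        rowSums(items[, negative_items, drop = FALSE] >= 1)
    })
}

#' Generate the correlated auxiliary variable and binary outcome
#'
#' The auxiliary variable emulates a second-wave GHQ measured one wave later:
#' a fresh 12-item table is generated from a person latent correlated (at the
#' profile's \code{latent_correlation}) with the supplied first-wave latent,
#' Likert-scored, and binned into the conventional four severity categories
#' 0--5 (low), 6--8 (moderate), 9--11 (high), 12--36 (very high). The binary
#' outcome (a living-at-home indicator) is drawn
#' Bernoulli(expit(intercept + slope * latent)).
#'
#' @param latent first-wave person latent vector.
#' @param profile a [synth_profile()]; the wave-9 items always use the
#'   mild-skew (\code{likert_like}) thresholds since the categories are
#'   defined on the Likert 0--36 scale.
#' @param seed integer seed.
#' @return list with \code{aux} (ordered factor with levels low, moderate,
#'   high, very_high) and \code{outcome} (0/1 integer vector).
#' @export
generate_aux_outcome <- function(latent, profile, seed) {
  stopifnot(inherits(profile, "synth_profile"))
  n <- length(latent)
  set.seed(seed)
  rho <- profile$latent_correlation
  latent9 <- rho * latent + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  wave9 <- synth_profile("likert_like",
                         latent_correlation = rho,
                         negative_items = profile$negative_items)
  items9 <- items_from_latent(latent9, wave9)
  lik9 <- rowSums(items9)
  aux <- cut(lik9, breaks = c(-0.5, 5.5, 8.5, 11.5, 36.5),
             labels = c("low", "moderate", "high", "very_high"),
             ordered_result = TRUE)
  p <- stats::plogis(profile$outcome_intercept + profile$outcome_slope * latent)
  outcome <- stats::rbinom(n, 1L, p)
  list(aux = aux, outcome = outcome)
}

#' Assemble a complete synthetic dataset
#'
#' Bundles a bounded score (with its possible range), the binary outcome and
#' the 4-level ordinal auxiliary into the complete "truth" dataset that the
#' missingness-resampling simulation repeatedly perturbs.
#'
#' @param n sample size (default 714).
#' @param profile a [synth_profile()] or profile name.
#' @param method scoring rule; defaults to the profile's natural rule
#'   (\code{likert_like} to \code{likert}, \code{cghq_like} to \code{cghq},
#'   \code{standard_like} to \code{standard}).
#' @param seed integer seed.
#' @return an object of class \code{complete_dataset}: list with
#'   \code{score}, \code{lo}, \code{hi}, \code{outcome}, \code{aux},
#'   \code{n}, plus the generating \code{profile} and \code{method}.
#' @examples
#' d <- make_dataset(714, "standard_like", seed = 1)
#' mean(d$score == 0)
#' @export
make_dataset <- function(n = 714, profile = "likert_like", method = NULL,
                         seed = 1) {
  if (is.character(profile)) profile <- synth_profile(profile)
  stopifnot(inherits(profile, "synth_profile"))
  if (is.null(method))
    method <- switch(profile$name,
                     likert_like = "likert",
                     cghq_like = "cghq",
                     standard_like = "standard")
  method <- match.arg(method, c("likert", "standard", "cghq"))
  items <- generate_items(n, profile, seed)
  score <- score_items(items, method)
  ao <- generate_aux_outcome(items$latent, profile, seed + 1L)
  bounds <- if (method == "likert") c(0, 36) else c(0, 12)
  complete_dataset(score = score, lo = bounds[1], hi = bounds[2],
                   outcome = ao$outcome, aux = ao$aux,
                   profile = profile$name, method = method)
}

#' Construct and validate a complete dataset
#'
#' @param score numeric score vector (may contain \code{NA} only for
#'   incomplete datasets produced by [set_missing()]).
#' @param lo,hi the possible range of the score.
#' @param outcome 0/1 vector, fully observed.
#' @param aux ordered factor (or codes coercible to one) with levels
#'   low, moderate, high, very_high; fully observed.
#' @param profile,method optional provenance labels.
#' @return object of class \code{complete_dataset}.
#' @export
complete_dataset <- function(score, lo, hi, outcome, aux,
                             profile = NA_character_, method = NA_character_) {
  n <- length(score)
  if (!is.factor(aux))
    aux <- factor(c("low", "moderate", "high", "very_high")[as.integer(aux)],
                  levels = c("low", "moderate", "high", "very_high"),
                  ordered = TRUE)
  aux <- factor(aux, levels = c("low", "moderate", "high", "very_high"),
                ordered = TRUE)
  stopifnot(length(outcome) == n, length(aux) == n, lo < hi)
  if (!all(outcome %in% 0:1)) stop("outcome must be binary 0/1")
  if (anyNA(aux) || anyNA(outcome))
    stop("outcome and auxiliary must be fully observed")
  ok <- is.na(score) | (score >= lo & score <= hi)
  if (!all(ok)) stop("scores must lie within [lo, hi]")
  structure(list(score = as.numeric(score), lo = lo, hi = hi,
                 outcome = as.integer(outcome), aux = aux, n = n,
                 profile = profile, method = method),
            class = "complete_dataset")
}

#' @export
print.complete_dataset <- function(x, ...) {
  nmis <- sum(is.na(x$score))
  cat("complete_dataset: n =", x$n, " score range [", x$lo, ",", x$hi, "]\n")
  if (!is.na(x$profile)) cat("  profile:", x$profile, " scoring:", x$method, "\n")
  cat("  score mean", round(mean(x$score, na.rm = TRUE), 3),
      " skewness", round(sample_skewness(x$score[!is.na(x$score)]), 3), "\n")
  cat("  outcome prevalence", round(mean(x$outcome), 3),
      " aux:", paste(levels(x$aux), table(x$aux), sep = "=", collapse = " "), "\n")
  if (nmis > 0) cat("  missing scores:", nmis, "\n")
  invisible(x)
}

#' Moment coefficient of skewness
#'
#' The biased moment coefficient \eqn{g_1 = m_3 / m_2^{3/2}} used throughout
#' the package, including as the zero-skewness criterion of the shifted-log
#' transform.
#'
#' @param x numeric vector.
#' @return the sample skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
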