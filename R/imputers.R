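#' Imputation-model design matrix
#'
#' The univariate imputation model regresses the incomplete score on the
#' fully observed binary outcome and the 4-level ordinal auxiliary entered
#' as three indicator columns (moderate, high, very_high; low is the
#' reference), plus an intercept.
#'
#' @param outcome binary vector.
#' @param aux 4-level ordinal vector.
#' @return n x 5 numeric matrix.
#' @export
design_matrix <- function(outcome, aux) {
  cbind(intercept = 1,
        outcome = as.numeric(outcome),
        aux_moderate = as.numeric(aux == "moderate"),
        aux_high = as.numeric(aux == "high"),
        aux_very_high = as.numeric(aux == "very_high"))
}

#' Posterior parameter draw for Bayesian linear-regression imputation
#'
#' The standard proper-imputation draw under the noninformative prior:
#' \eqn{\sigma^{*2} = RSS / \chi^2_{\nu}} with \eqn{\nu = n_{obs} - p}, then
#' \eqn{\beta^* \sim N(\hat\beta, \sigma^{*2} (X'X)^{-1})} around the
#' least-squares fit. Consumes the current RNG stream.
#'
#' @param y_obs observed responses.
#' @param X_obs design matrix rows for the observed cases.
#' @return object of class \code{parameter_draw}: \code{beta_star},
#'   \code{sigma_star}, plus the underlying \code{beta_hat} and \code{qr}.
#' @export
draw_bayes_linreg <- function(y_obs, X_obs) {
  ls <- linreg_fit(y_obs, X_obs)
  nu <- length(y_obs) - ls$p
  sigma_star <- sqrt(ls$rss / stats::rchisq(1, nu))
  # (X'X)^{-1} = R^{-1} R^{-T}: draw via one triangular solve
  beta_star <- ls$beta_hat +
    sigma_star * backsolve(ls$R, stats::rnorm(ls$p))
  structure(list(beta_star = drop(beta_star), sigma_star = sigma_star,
                 beta_hat = ls$beta_hat, source = "bayes_normal"),
            class = "parameter_draw")
}

# least-squares fit via QR; shared by the regression-based imputers
linreg_fit <- function(y_obs, X_obs) {
  p <- ncol(X_obs)
  if (length(y_obs) <= p) stop("too few observed cases for the design")
  qr_x <- qr(X_obs)
  if (qr_x$rank < p) stop("design matrix is rank deficient on observed rows")
  beta_hat <- qr.coef(qr_x, y_obs)
  res <- y_obs - drop(X_obs %*% beta_hat)
  rss <- sum(res^2)
  if (rss <= .Machine$double.eps * sum(y_obs^2))
    stop("residual sum of squares is zero; degenerate imputation model")
  list(beta_hat = beta_hat, rss = rss, p = p, R = qr.R(qr_x), qr = qr_x)
}

#' Linear-regression imputation (one copy, no rounding)
#'
#' Fills each missing entry with \eqn{x_i'\beta^* + \sigma^* z_i} using a
#' fresh standard-normal \eqn{z_i} and a fresh [draw_bayes_linreg()]
#' parameter draw. Values outside the score range are retained.
#'
#' @param y score vector with \code{NA} at missing entries (or complete, with
#'   \code{mask} indicating the entries to impute).
#' @param X full design matrix.
#' @param mask logical vector of entries to impute; defaults to
#'   \code{is.na(y)}.
#' @param draw optional precomputed \code{parameter_draw}.
#' @return the completed score vector.
#' @export
impute_regress <- function(y, X, mask = is.na(y), draw = NULL) {
  if (!any(mask)) return(y)
  if (is.null(draw)) draw <- draw_bayes_linreg(y[!mask], X[!mask, , drop = FALSE])
  mu <- drop(X[mask, , drop = FALSE] %*% draw$beta_star)
  y[mask] <- mu + draw$sigma_star * stats::rnorm(sum(mask))
  y
}

#' Clamp imputed values to the range limits
#'
#' Post-imputation rounding in the range-restriction sense: values below
#' \code{lo} are set to \code{lo} and values above \code{hi} to \code{hi}.
#' Only entries flagged in \code{mask} (the imputed ones) are touched.
#'
#' @param y completed score vector.
#' @param lo,hi range limits, \code{lo < hi}.
#' @param mask entries eligible for clamping; defaults to all.
#' @return the clamped vector.
#' @export
round_to_bounds <- function(y, lo, hi, mask = rep(TRUE, length(y))) {
  stopifnot(lo < hi)
  y[mask] <- pmin(hi, pmax(lo, y[mask]))
  y
}

#' Predictive-mean-matching imputation (one copy)
#'
#' Type-1 matching: predicted means for the missing cases use a fresh
#' Bayesian parameter draw \eqn{\beta^*}, donors' predicted means use the
#' least-squares \eqn{\hat\beta}. For each missing case the \code{k} observed
#' donors with the smallest absolute difference in predicted mean are found
#' (ties broken by position after a seeded shuffle of the donor order) and
#' one donor's observed value is copied uniformly at random. Type-0 matching
#' (donor predictions also from \eqn{\beta^*}) is available as a variant.
#'
#' @inheritParams impute_regress
#' @param k number of nearest donors (default 5).
#' @param matching \code{"type1"} (default) or \code{"type0"}.
#' @return the completed score vector; imputed entries are always elements
#'   of the observed set, hence within range.
#' @export
impute_pmm <- function(y, X, mask = is.na(y), k = 5, matching = c("type1", "type0")) {
  matching <- match.arg(matching)
  if (!any(mask)) return(y)
  y_obs <- y[!mask]
  n_obs <- length(y_obs)
  if (k > n_obs) stop("k exceeds the number of observed donors")
  X_obs <- X[!mask, , drop = FALSE]
  draw <- draw_bayes_linreg(y_obs, X_obs)
  pred_mis <- drop(X[mask, , drop = FALSE] %*% draw$beta_star)
  beta_don <- if (matching == "type1") draw$beta_hat else draw$beta_star
  pred_obs <- drop(X_obs %*% beta_don)
  perm <- sample.int(n_obs)          # seeded shuffle for tie-breaking
  pred_perm <- pred_obs[perm]
  y_perm <- y_obs[perm]
  filled <- vapply(pred_mis, function(ph) {
    idx <- order(abs(pred_perm - ph))[seq_len(k)]
    y_perm[idx[sample.int(k, 1)]]
  }, numeric(1))
  y[mask] <- filled
  y
}

#' Multiply impute an incomplete dataset
#'
#' Orchestrates \code{m} independent imputation copies of the score by one of
#' the four univariate methods, on the raw or the zero-skewness transformed
#' scale. Each copy uses its own fresh parameter draw, so between-imputation
#' variance reflects parameter uncertainty (proper imputation).
#'
#' On the transformed scale the shift is fitted on the observed
#' (post-missingness) values, the range limits are mapped to the transformed
#' scale, imputation runs there (with the mapped bounds wherever the method
#' uses bounds), and imputed values are back-transformed exactly; values
#' beyond the bounds are never clipped on back-transformation. Out-of-range
#' counts per copy are recorded on the imputation scale before any rounding.
#'
#' @param data a \code{complete_dataset} whose score contains \code{NA} at
#'   the missing entries (see [set_missing()]).
#' @param method one of \code{"regress"} (linear regression, no rounding),
#'   \code{"regress_round"} (then clamped to the limits),
#'   \code{"truncreg"} (truncated normal regression), \code{"pmm"}
#'   (predictive mean matching).
#' @param scale \code{"raw"} or \code{"transformed"}.
#' @param m number of imputations (default 20).
#' @param k donor count for PMM.
#' @param matching PMM matching variant.
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used.
#' @return object of class \code{completed_set}: \code{imputations} (n x m
#'   matrix on the raw scale), per-copy out-of-range counts \code{n_below}
#'   and \code{n_above}, \code{n_missing}, \code{method}, \code{scale},
#'   \code{mask}, bounds, and the fitted transform (if any).
#' @export
multiple_impute <- function(data, method = c("regress", "regress_round",
                                             "truncreg", "pmm"),
                            scale = c("raw", "transformed"), m = 20,
                            k = 5, matching = "type1", seed = NULL) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  stopifnot(inherits(data, "complete_dataset"), m >= 2)
  if (!is.null(seed)) set.seed(seed)
  mask <- is.na(data$score)
  X <- design_matrix(data$outcome, data$aux)
  y <- data$score
  lo <- data$lo; hi <- data$hi
  ts <- NULL
  if (scale == "transformed") {
    ts <- fit_zero_skew(y[!mask], lo, hi)
    y[!mask] <- zs_apply(y[!mask], ts)
    lo <- ts$lo_t; hi <- ts$hi_t
  }
  n_mis <- sum(mask)
  imps <- matrix(rep(data$score, m), ncol = m)
  n_below <- integer(m); n_above <- integer(m)
  if (n_mis > 0) {
    tfit <- if (method == "truncreg")
      fit_truncreg(y[!mask], X[!mask, , drop = FALSE], lo, hi)
    for (j in seq_len(m)) {
      yj <- switch(method,
        regress = ,
        regress_round = impute_regress(y, X, mask),
        truncreg = impute_truncreg(tfit, y, X, mask, lo, hi),
        pmm = impute_pmm(y, X, mask, k = k, matching = matching))
      n_below[j] <- sum(yj[mask] < lo)
      n_above[j] <- sum(yj[mask] > hi)
      if (method == "regress_round") yj <- round_to_bounds(yj, lo, hi, mask)
      if (scale == "transformed") yj[mask] <- zs_invert(yj[mask], ts)
      imps[mask, j] <- yj[mask]
    }
  }
  structure(list(imputations = imps, n_below = n_below, n_above = n_above,
                 n_missing = n_mis, method = method, scale = scale,
                 mask = mask, lo = data$lo, hi = data$hi, transform = ts,
                 m = m),
            class = "completed_set")
}

#' @export
print.completed_set <- function(x, ...) {
  cat("completed_set:", x$m, "imputations by", x$method, "on the", x$scale,
      "scale;", x$n_missing, "missing\n")
  if (x$n_missing > 0)
    cat("  mean % imputed below/above range:",
        round(100 * mean(x$n_below) / x$n_missing, 2), "/",
        round(100 * mean(x$n_above) / x$n_missing, 2), "\n")
  invisible(x)
}
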