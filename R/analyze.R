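#' Complete-data analysis: marginal mean
#'
#' @param score complete numeric vector.
#' @return object of class \code{estimate_se}: \code{estimate} (sample
#'   mean), \code{variance} (\eqn{s^2/n} with unbiased \eqn{s^2}), and the
#'   parameter label.
#' @export
analyze_marginal_mean <- function(score) {
  if (anyNA(score)) stop("score must be complete")
  n <- length(score)
  if (n < 2) stop("need at least two observations")
  v <- stats::var(score) / n
  if (v == 0) stop("degenerate constant score; variance is zero")
  estimate_se(mean(score), v, "marginal_mean")
}

#' Complete-data analysis: univariable logistic regression slope
#'
#' Fits \eqn{\mathrm{logit}\,P(outcome = 1) = \gamma_0 + \gamma_1 score} by
#' Newton--Raphson (tolerance 1e-8 on the slope update) and returns the
#' slope with its squared asymptotic standard error from the inverse
#' observed information.
#'
#' @param outcome binary vector with both classes present.
#' @param score complete numeric vector.
#' @return an \code{estimate_se} with parameter \code{"log_odds_ratio"}.
#' @export
analyze_logistic <- function(outcome, score) {
  if (anyNA(score) || anyNA(outcome)) stop("inputs must be complete")
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  X <- cbind(1, score)
  beta <- c(stats::qlogis(mean(outcome)), 0)
  for (iter in 1:50) {
    eta <- drop(X %*% beta)
    if (any(abs(eta) > 30)) stop("separation suspected; fit diverged")
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    delta <- solve(info, crossprod(X, outcome - p))
    beta <- beta + drop(delta)
    if (abs(delta[2]) < 1e-8) {
      v <- solve(info)[2, 2]
      return(estimate_se(unname(beta[2]), unname(v), "log_odds_ratio"))
    }
  }
  stop("logistic Newton-Raphson did not converge")
}

estimate_se <- function(estimate, variance, parameter) {
  if (variance <= 0) stop("variance must be positive")
  structure(list(estimate = estimate, variance = variance,
                 parameter = parameter),
            class = "estimate_se")
}

#' @export
print.estimate_se <- function(x, ...) {
  cat(x$parameter, ": estimate", format(x$estimate, digits = 6),
      " SE", format(sqrt(x$variance), digits = 6), "\n")
  invisible(x)
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines the \code{m} completed-data estimates: \eqn{\bar Q_m} is their
#' mean, \eqn{\bar U_m} the mean within-imputation variance, \eqn{B_m} the
#' unbiased between-imputation variance, total variance \eqn{\bar U_m +
#' (1 + 1/m) B_m}. The confidence interval uses the t distribution with
#' \eqn{m - 1} degrees of freedom; the classical Rubin large-sample degrees
#' of freedom are available as an option.
#'
#' Two interval constructions are available. The default, \code{"between"},
#' is the one used throughout the missingness-resampling evaluation: because
#' the complete-data estimate \eqn{\hat Q} is held fixed and only the
#' missingness is redrawn, the sampling variability of \eqn{\bar Q_m} around
#' \eqn{\hat Q} is the between-imputation component alone, and the interval
#' is \eqn{\bar Q_m \mp t_{m-1,0.975} \sqrt{(1 + 1/m) B_m}}. The
#' \code{"total"} construction is the classical Rubin interval based on
#' \eqn{\sqrt{\bar U_m + (1+1/m) B_m}}, appropriate when the estimand is the
#' population parameter rather than a fixed complete-data statistic.
#'
#' @param per_copy list of \code{estimate_se} objects (one per imputation),
#'   all for the same parameter; alternatively supply \code{estimates} and
#'   \code{variances} vectors directly.
#' @param estimates,variances numeric vectors of per-copy point estimates
#'   and squared standard errors (used when \code{per_copy} is missing).
#' @param interval \code{"between"} (default; between-imputation variance
#'   only, t with m-1 df) or \code{"total"} (classical Rubin total
#'   variance).
#' @param df \code{"m_minus_1"} (default) or \code{"rubin"} for
#'   \eqn{\nu = (m-1)(1 + \bar U_m / ((1+1/m)B_m))^2}.
#' @param level confidence level.
#' @return object of class \code{pooled_result}: \code{q_bar}, \code{u_bar},
#'   \code{b_m}, \code{total_var}, \code{ci_lo}, \code{ci_hi}, \code{m}.
#' @examples
#' rubin_pool(estimates = c(1, 3), variances = c(1, 1))
#' @export
rubin_pool <- function(per_copy = NULL, estimates = NULL, variances = NULL,
                       interval = c("between", "total"),
                       df = c("m_minus_1", "rubin"), level = 0.95) {
  interval <- match.arg(interval)
  df <- match.arg(df)
  if (!is.null(per_copy)) {
    pars <- vapply(per_copy, `[[`, character(1), "parameter")
    if (length(unique(pars)) > 1)
      stop("cannot pool estimates of different parameters")
    estimates <- vapply(per_copy, `[[`, numeric(1), "estimate")
    variances <- vapply(per_copy, `[[`, numeric(1), "variance")
  }
  m <- length(estimates)
  if (m < 2 || length(variances) != m)
    stop("need m >= 2 matched estimates and variances")
  q_bar <- mean(estimates)
  u_bar <- mean(variances)
  b_m <- stats::var(estimates)
  total <- u_bar + (1 + 1 / m) * b_m
  nu <- if (df == "m_minus_1" || b_m == 0) m - 1 else
    (m - 1) * (1 + u_bar / ((1 + 1 / m) * b_m))^2
  tq <- stats::qt(1 - (1 - level) / 2, nu)
  half <- tq * sqrt(if (interval == "between") (1 + 1 / m) * b_m else total)
  structure(list(q_bar = q_bar, u_bar = u_bar, b_m = b_m, total_var = total,
                 ci_lo = q_bar - half, ci_hi = q_bar + half, m = m, df = nu),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat("pooled_result (m =", x$m, "): Q-bar", format(x$q_bar, digits = 6),
      " total var", format(x$total_var, digits = 6), "\n")
  cat("  95% CI [", format(x$ci_lo, digits = 6), ",",
      format(x$ci_hi, digits = 6), "]  (t df", format(x$df, digits = 4), ")\n")
  invisible(x)
}

# per-copy analyses for a whole completed_set, vectorized where possible
analyze_copies <- function(completed, parameter, outcome = NULL) {
  Y <- completed$imputations
  n <- nrow(Y)
  if (parameter == "marginal_mean") {
    est <- colMeans(Y)
    v <- (colSums(Y^2) - n * est^2) / ((n - 1) * n)
    list(estimates = est, variances = v)
  } else if (parameter == "log_odds_ratio") {
    res <- apply(Y, 2, function(y) {
      fit <- analyze_logistic(outcome, y)
      c(fit$estimate, fit$variance)
    })
    list(estimates = res[1, ], variances = res[2, ])
  } else stop("unknown parameter: ", parameter)
}
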