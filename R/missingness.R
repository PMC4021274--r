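#' Specify a missingness mechanism for the score
#'
#' Under MCAR a fixed number of scores, \code{round(prop * n)}, is deleted by
#' simple random sampling. Under MAR each score is deleted independently with
#' probability
#' \deqn{p_i = \mathrm{expit}(\alpha + \beta_1 Living_i + \beta_2 1\{aux_i =
#' moderate\} + \beta_3 1\{aux_i = high\} + \beta_4 1\{aux_i = very\_high\})}
#' with the low auxiliary category as reference. The slope defaults are
#' \eqn{\beta_1 = 1.25} (odds ratio 3.5) and \eqn{\beta_2, \beta_3, \beta_4 =
#' 0.2, 0.3, 0.4} (odds ratios 1.22, 1.35, 1.5); the intercept \eqn{\alpha}
#' is left unset and must be calibrated with [calibrate_alpha()] so the mean
#' deletion probability equals \code{prop}.
#'
#' @param mechanism \code{"MCAR"} or \code{"MAR"}.
#' @param prop target missingness proportion in (0,1); default 0.33.
#' @param beta_living coefficient on the binary outcome.
#' @param beta_aux length-3 coefficients for the moderate, high and very_high
#'   auxiliary categories.
#' @param alpha intercept; \code{NA} until calibrated.
#' @return object of class \code{missingness_spec}.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR"), prop = 0.33,
                             beta_living = 1.25,
                             beta_aux = c(moderate = 0.2, high = 0.3,
                                          very_high = 0.4),
                             alpha = NA_real_) {
  mechanism <- match.arg(mechanism)
  stopifnot(prop > 0, prop < 1, length(beta_aux) == 3)
  structure(list(mechanism = mechanism, prop = prop,
                 beta_living = beta_living,
                 beta_aux = stats::setNames(as.numeric(beta_aux),
                                            c("moderate", "high", "very_high")),
                 alpha = alpha),
            class = "missingness_spec")
}

#' @export
print.missingness_spec <- function(x, ...) {
  cat("missingness_spec:", x$mechanism, " target proportion", x$prop, "\n")
  if (x$mechanism == "MAR")
    cat("  beta: living", x$beta_living, " aux",
        paste(names(x$beta_aux), x$beta_aux, sep = "=", collapse = " "),
        " alpha", if (is.na(x$alpha)) "(uncalibrated)" else round(x$alpha, 6),
        "\n")
  invisible(x)
}

# linear predictor excluding the intercept
mar_eta <- function(outcome, aux, spec) {
  spec$beta_living * outcome +
    spec$beta_aux["moderate"] * (aux == "moderate") +
    spec$beta_aux["high"] * (aux == "high") +
    spec$beta_aux["very_high"] * (aux == "very_high")
}

#' Per-unit MAR missingness probabilities
#'
#' @param outcome binary vector.
#' @param aux 4-level ordinal vector (levels low, moderate, high, very_high).
#' @param spec a [missingness_spec()] with \code{alpha} set.
#' @return probability vector.
#' @export
mar_probability <- function(outcome, aux, spec) {
  if (is.na(spec$alpha)) stop("alpha is unset; run calibrate_alpha() first")
  stats::plogis(spec$alpha + unname(mar_eta(outcome, aux, spec)))
}

#' Calibrate the MAR intercept to the target missingness proportion
#'
#' Solves \eqn{\mathrm{mean}_i\, p_i(\alpha) = prop} for \eqn{\alpha} by
#' monotone root finding (the mean probability is continuous and strictly
#' increasing in \eqn{\alpha}), to absolute tolerance 1e-6 on the mean
#' probability.
#'
#' @param data a \code{complete_dataset}.
#' @param spec a [missingness_spec()] with mechanism MAR.
#' @return the spec with \code{alpha} filled in.
#' @export
calibrate_alpha <- function(data, spec) {
  stopifnot(inherits(data, "complete_dataset"))
  eta <- unname(mar_eta(data$outcome, data$aux, spec))
  f <- function(a) mean(stats::plogis(a + eta)) - spec$prop
  root <- stats::uniroot(f, interval = c(-50, 50), tol = 1e-12)
  spec$alpha <- root$root
  if (abs(f(spec$alpha)) > 1e-6)
    stop("alpha calibration did not reach tolerance")
  spec
}

#' Impose missingness on the score
#'
#' MCAR deletes exactly \code{round(prop * n)} scores chosen by simple random
#' sampling without replacement; MAR deletes each score by an independent
#' Bernoulli draw with the calibrated per-unit probability. Only the score is
#' ever masked; outcome and auxiliary stay complete.
#'
#' @param data a \code{complete_dataset}.
#' @param spec a [missingness_spec()] (calibrated, if MAR).
#' @param seed integer seed; the mask is reproducible given the seed.
#' @return object of class \code{missing_mask}: logical \code{mask}
#'   (\code{TRUE} = score missing), \code{mechanism}, \code{realized_prop}.
#' @export
impose_missingness <- function(data, spec, seed) {
  stopifnot(inherits(data, "complete_dataset"),
            inherits(spec, "missingness_spec"))
  set.seed(seed)
  n <- data$n
  mask <- logical(n)
  if (spec$mechanism == "MCAR") {
    mask[sample.int(n, round(spec$prop * n))] <- TRUE
  } else {
    p <- mar_probability(data$outcome, data$aux, spec)
    mask <- stats::runif(n) < p
  }
  structure(list(mask = mask, mechanism = spec$mechanism,
                 realized_prop = mean(mask)),
            class = "missing_mask")
}

#' Blank out masked scores
#'
#' @param data a \code{complete_dataset}.
#' @param mask a \code{missing_mask} or logical vector.
#' @return the dataset with masked score entries set to \code{NA}.
#' @export
set_missing <- function(data, mask) {
  if (inherits(mask, "missing_mask")) mask <- mask$mask
  stopifnot(length(mask) == data$n)
  data$score[mask] <- NA_real_
  data
}
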