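#' Configure a missingness-resampling scenario
#'
#' A scenario fixes one complete synthetic dataset and repeatedly deletes
#' and re-imputes the score, benchmarking every imputation method against
#' the complete-data statistics of that same dataset.
#'
#' @param profile synthetic profile name (or [synth_profile()]).
#' @param method scoring rule; \code{NULL} for the profile's natural rule.
#' @param mechanism \code{"MCAR"} or \code{"MAR"}.
#' @param N number of missingness replicates (default 1000).
#' @param m imputations per replicate (default 20).
#' @param methods imputation methods to run.
#' @param scales imputation scales to run (\code{"raw"},
#'   \code{"transformed"}).
#' @param parameters target parameters (\code{"marginal_mean"},
#'   \code{"log_odds_ratio"}).
#' @param prop target missingness proportion.
#' @param k PMM donor count.
#' @param n sample size of the synthetic dataset.
#' @param seed master seed; per-replicate seeds are derived from it as a
#'   logged substream.
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(profile = "likert_like", method = NULL,
                            mechanism = c("MCAR", "MAR"), N = 1000, m = 20,
                            methods = c("regress", "regress_round",
                                        "truncreg", "pmm"),
                            scales = "raw",
                            parameters = c("marginal_mean", "log_odds_ratio"),
                            prop = 0.33, k = 5, n = 714, seed = 1) {
  mechanism <- match.arg(mechanism)
  methods <- match.arg(methods, c("regress", "regress_round", "truncreg",
                                  "pmm"), several.ok = TRUE)
  scales <- match.arg(scales, c("raw", "transformed"), several.ok = TRUE)
  parameters <- match.arg(parameters, c("marginal_mean", "log_odds_ratio"),
                          several.ok = TRUE)
  stopifnot(N >= 2, m >= 2, n >= 10)
  structure(list(profile = profile, method = method, mechanism = mechanism,
                 N = N, m = m, methods = methods, scales = scales,
                 parameters = parameters, prop = prop, k = k, n = n,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", if (is.character(x$profile)) x$profile else
      x$profile$name, "/", x$mechanism, " N =", x$N, " m =", x$m, "\n")
  cat("  methods:", paste(x$methods, collapse = ", "),
      " scales:", paste(x$scales, collapse = ", "), "\n")
  invisible(x)
}

# per-replicate seeds: a reproducible, logged substream of the master seed
replicate_seeds <- function(seed, N) {
  set.seed(seed)
  sample.int(2147483646L, N)
}

#' Run one missingness replicate
#'
#' Deletes scores according to the (pre-calibrated) missingness
#' specification with the given replicate seed, then runs every configured
#' method x scale, analyses each completed copy and pools by Rubin's rules.
#' Re-running with the same replicate seed reproduces the replicate exactly.
#'
#' @param data the complete dataset.
#' @param spec calibrated \code{missingness_spec}.
#' @param config a [scenario_config()].
#' @param rep_seed integer seed for this replicate.
#' @return nested list: per method x scale either a failure record or, per
#'   parameter, the pooled result plus out-of-range counts.
#' @export
run_replicate <- function(data, spec, config, rep_seed) {
  mask <- impose_missingness(data, spec, rep_seed)
  incomplete <- set_missing(data, mask)
  out <- list()
  for (sc in config$scales) {
    for (meth in config$methods) {
      key <- paste(meth, sc, sep = ".")
      cell <- tryCatch({
        cs <- multiple_impute(incomplete, method = meth, scale = sc,
                              m = config$m, k = config$k)
        pooled <- lapply(config$parameters, function(par) {
          a <- analyze_copies(cs, par, outcome = data$outcome)
          rubin_pool(estimates = a$estimates, variances = a$variances)
        })
        names(pooled) <- config$parameters
        list(failed = FALSE, pooled = pooled,
             pct_below = 100 * mean(cs$n_below) / max(1, cs$n_missing),
             pct_above = 100 * mean(cs$n_above) / max(1, cs$n_missing))
      }, error = function(e) list(failed = TRUE, message = conditionMessage(e)))
      out[[key]] <- cell
    }
  }
  out
}

#' Run a full missingness-resampling scenario
#'
#' Computes the complete-data estimates once, calibrates the MAR intercept
#' once (if needed), then runs \code{N} replicates of delete-impute-pool and
#' aggregates the performance measures: mean MI estimate \eqn{E[\bar Q_m]},
#' bias \eqn{E[\bar Q_m] - \hat Q}, mean within-imputation variance
#' \eqn{E[\bar U_m]}, empirical variance of \eqn{\bar Q_m} across
#' replicates, the between-imputation estimate \eqn{(1 + 1/m) E[B_m]},
#' coverage of the nominal 95% intervals, and the average percentages of
#' values imputed outside the range (recorded pre-rounding). Replicates
#' where a method fails (e.g. truncated-regression non-convergence) are
#' excluded for that method and counted.
#'
#' @param config a [scenario_config()].
#' @param data optional pre-built \code{complete_dataset}; by default one is
#'   generated from the config's profile, sample size and seed.
#' @param verbose print progress every 100 replicates.
#' @return a \code{performance_report}: data frame with one row per
#'   parameter x method x scale, with attributes \code{q_hat}, \code{u}
#'   (complete-data statistics), \code{alpha}, \code{rep_seeds} and
#'   \code{config}.
#' @export
run_scenario <- function(config, data = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(data))
    data <- make_dataset(config$n, config$profile, config$method,
                         seed = config$seed)
  complete_fit <- lapply(config$parameters, function(par)
    switch(par,
           marginal_mean = analyze_marginal_mean(data$score),
           log_odds_ratio = analyze_logistic(data$outcome, data$score)))
  names(complete_fit) <- config$parameters

  spec <- missingness_spec(config$mechanism, prop = config$prop)
  if (config$mechanism == "MAR") spec <- calibrate_alpha(data, spec)
  seeds <- replicate_seeds(config$seed, config$N)

  keys <- as.vector(outer(config$methods, config$scales, paste, sep = "."))
  acc <- lapply(keys, function(k)
    list(n_failed = 0L, pct_below = numeric(0), pct_above = numeric(0),
         per_par = stats::setNames(
           lapply(config$parameters, function(p)
             list(q_bar = numeric(0), u_bar = numeric(0), b_m = numeric(0),
                  covered = logical(0))),
           config$parameters)))
  names(acc) <- keys

  for (r in seq_len(config$N)) {
    rep_out <- run_replicate(data, spec, config, seeds[r])
    for (key in keys) {
      cell <- rep_out[[key]]
      if (cell$failed) {
        acc[[key]]$n_failed <- acc[[key]]$n_failed + 1L
        next
      }
      acc[[key]]$pct_below <- c(acc[[key]]$pct_below, cell$pct_below)
      acc[[key]]$pct_above <- c(acc[[key]]$pct_above, cell$pct_above)
      for (par in config$parameters) {
        p <- cell$pooled[[par]]
        qh <- complete_fit[[par]]$estimate
        a <- acc[[key]]$per_par[[par]]
        a$q_bar <- c(a$q_bar, p$q_bar)
        a$u_bar <- c(a$u_bar, p$u_bar)
        a$b_m <- c(a$b_m, p$b_m)
        a$covered <- c(a$covered, p$ci_lo <= qh && qh <= p$ci_hi)
        acc[[key]]$per_par[[par]] <- a
      }
    }
    if (verbose && r %% 100 == 0)
      message("replicate ", r, " / ", config$N)
  }

  rows <- list()
  for (par in config$parameters) {
    for (sc in config$scales) {
      for (meth in config$methods) {
        key <- paste(meth, sc, sep = ".")
        a <- acc[[key]]$per_par[[par]]
        qh <- complete_fit[[par]]$estimate
        if (length(a$q_bar) < 2) {
          rows[[length(rows) + 1]] <- data.frame(
            parameter = par, method = meth, scale = sc,
            e_q_bar = NA_real_, bias = NA_real_, e_u_bar = NA_real_,
            var_q_bar = NA_real_, between_est = NA_real_,
            coverage = NA_real_, pct_below = NA_real_, pct_above = NA_real_,
            n_failed = acc[[key]]$n_failed)
          next
        }
        vc <- mi_variance_checks(a$q_bar, a$u_bar, a$b_m, config$m)
        oor_meth <- meth %in% c("regress", "regress_round")
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, method = meth, scale = sc,
          e_q_bar = mean(a$q_bar), bias = mi_bias(mean(a$q_bar), qh),
          e_u_bar = vc[["e_u_bar"]], var_q_bar = vc[["var_q_bar"]],
          between_est = vc[["between_est"]],
          coverage = mean(a$covered),
          pct_below = if (oor_meth) mean(acc[[key]]$pct_below) else 0,
          pct_above = if (oor_meth) mean(acc[[key]]$pct_above) else 0,
          n_failed = acc[[key]]$n_failed)
      }
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "q_hat") <- vapply(complete_fit, `[[`, numeric(1), "estimate")
  attr(report, "u") <- vapply(complete_fit, `[[`, numeric(1), "variance")
  attr(report, "alpha") <- spec$alpha
  attr(report, "rep_seeds") <- seeds
  attr(report, "config") <- config
  class(report) <- c("performance_report", "data.frame")
  report
}

#' @export
print.performance_report <- function(x, digits = 4, ...) {
  cfg <- attr(x, "config")
  qh <- attr(x, "q_hat"); u <- attr(x, "u")
  cat("Missingness-resampling performance report (",
      cfg$mechanism, ", N = ", cfg$N, ", m = ", cfg$m, ")\n", sep = "")
  for (par in names(qh))
    cat("  ", par, ": Q-hat = ", format(qh[par], digits = 6),
        "  U = ", format(u[par], digits = 4), "\n", sep = "")
  print.data.frame(cbind(x[1:3],
                         round(x[4:ncol(x)], digits)), row.names = FALSE)
  invisible(x)
}

#' Bias of the mean MI estimate
#'
#' Signed difference \eqn{E[\bar Q_m] - \hat Q} between the average pooled
#' estimate over replicates and the complete-data estimate.
#'
#' @param e_q_bar mean over replicates of the pooled estimate.
#' @param q_hat complete-data estimate.
#' @return the signed bias.
#' @export
mi_bias <- function(e_q_bar, q_hat) e_q_bar - q_hat

#' Variance-calibration summaries over replicates
#'
#' Returns \code{e_u_bar} (mean within-imputation variance, to be compared
#' with the complete-data variance \eqn{U}), \code{var_q_bar} (empirical
#' variance of the pooled estimates across replicates) and
#' \code{between_est} \eqn{= (1 + 1/m) E[B_m]}, the two sides of the
#' between-imputation calibration identity.
#'
#' @param q_bars,u_bars,b_ms per-replicate pooled quantities.
#' @param m number of imputations.
#' @return named numeric vector.
#' @export
mi_variance_checks <- function(q_bars, u_bars, b_ms, m) {
  stopifnot(length(q_bars) >= 2)
  c(e_u_bar = mean(u_bars),
    var_q_bar = stats::var(q_bars),
    between_est = (1 + 1 / m) * mean(b_ms))
}

#' Coverage of nominal 95% MI intervals
#'
#' Fraction of replicates whose interval \eqn{\bar Q_m \mp t_{m-1,0.975}
#' \sqrt{\bar U_m + (1+1/m) B_m}} contains the complete-data estimate
#' (closed interval).
#'
#' @param pooled list of \code{pooled_result} objects (one per replicate).
#' @param q_hat complete-data estimate.
#' @return coverage proportion in [0, 1].
#' @export
mi_coverage <- function(pooled, q_hat) {
  hits <- vapply(pooled, function(p) p$ci_lo <= q_hat && q_hat <= p$ci_hi,
                 logical(1))
  mean(hits)
}

#' Average percentage of imputations outside the range
#'
#' Averages, over completed sets (replicates) and copies, the percentage of
#' imputed values below the lower and above the upper range limit, counted
#' on the imputation scale before any rounding.
#'
#' @param completed_sets list of \code{completed_set} objects.
#' @return named vector \code{c(pct_below, pct_above)}.
#' @export
pct_out_of_range <- function(completed_sets) {
  below <- vapply(completed_sets, function(cs)
    100 * mean(cs$n_below) / max(1, cs$n_missing), numeric(1))
  above <- vapply(completed_sets, function(cs)
    100 * mean(cs$n_above) / max(1, cs$n_missing), numeric(1))
  c(pct_below = mean(below), pct_above = mean(above))
}
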