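#' Bias of a set of coefficient estimates
#'
#' Mean of the estimates minus the true value. The Monte-Carlo standard
#' error of the mean, `sd(estimates)/sqrt(length(estimates))`, is attached
#' as the attribute `"mc_se"`.
#'
#' @param estimates Nonempty finite numeric vector of replicate estimates.
#' @param truth True (or pseudo-true) coefficient.
#' @return Scalar bias with attribute `"mc_se"`.
#' @export
estimate_bias <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("no successful fits")
  if (any(!is.finite(estimates))) stop("estimates must be finite")
  structure(mean(estimates) - truth,
            mc_se = stats::sd(estimates) / sqrt(length(estimates)))
}

#' Empirical confidence-interval coverage
#'
#' Fraction of intervals `[ci_lower, ci_upper]` containing the true value.
#' The binomial Monte-Carlo standard error `sqrt(p(1-p)/n)` is attached as
#' attribute `"mc_se"`.
#'
#' @param ci_lower,ci_upper Interval limits, equal length,
#'   `ci_lower <= ci_upper`.
#' @param truth True coefficient.
#' @return Proportion in `[0, 1]` with attribute `"mc_se"`.
#' @export
estimate_coverage <- function(ci_lower, ci_upper, truth) {
  if (length(ci_lower) == 0L) stop("no successful fits")
  stopifnot(length(ci_lower) == length(ci_upper))
  if (any(ci_lower > ci_upper)) stop("ci_lower must not exceed ci_upper")
  p <- mean(ci_lower <= truth & truth <= ci_upper)
  structure(p, mc_se = sqrt(p * (1 - p) / length(ci_lower)))
}

#' Summarise scenario results into a metrics table
#'
#' Collapses the raw per-replicate fits of one or more scenarios into the
#' long-format metrics table of the comparison study: one row per
#' (scenario, method, metric) with the metric value, its Monte-Carlo
#' standard error, and the number of effective (converged, successful)
#' replicates. Metrics are computed on the tracked coefficient only (CRP /
#' its continuous compartment in censored-covariate scenarios, the
#' treatment coefficient in censored-outcome scenarios). Non-converged fits
#' are excluded from the metrics but counted: for every scenario cell,
#' `reps_effective + failures = reps`.
#'
#' @param results A `bloq_scenario_results` or a list of them.
#' @param truth Optional named-by-nothing scalar truth; by default taken
#'   from each scenario via [true_target_coef()].
#'
#' @return Data frame with columns `model_id`, `setting`, `n`,
#'   `lloq_proportion`, `target_r2`, `method`, `metric`
#'   (`"bias"`/`"coverage"`/`"mse"`), `value`, `mc_se`, `reps_effective`,
#'   `failures`, `truth`.
#' @export
summarize_metrics <- function(results, truth = NULL) {
  if (inherits(results, "bloq_scenario_results")) results <- list(results)
  out <- lapply(results, summarize_one_scenario, truth = truth)
  do.call(rbind, out)
}

summarize_one_scenario <- function(res, truth = NULL) {
  cfg <- res$cfg
  if (is.null(truth)) truth <- true_target_coef(cfg)
  tgt <- res$fits[res$fits$is_target & res$fits$converged, , drop = FALSE]
  methods <- unique(c(res$fits$method, res$failures$method))
  rows <- lapply(methods, function(m) {
    sub <- tgt[tgt$method == m, , drop = FALSE]
    n_fail <- cfg$reps - nrow(sub)
    base <- data.frame(
      model_id = cfg$spec$model_id, setting = cfg$spec$setting, n = cfg$n,
      lloq_proportion = cfg$lloq_proportion, target_r2 = cfg$target_r2,
      method = m, stringsAsFactors = FALSE)
    metric_row <- function(metric, value, mc_se) {
      cbind(base, data.frame(metric = metric, value = value, mc_se = mc_se,
                             reps_effective = nrow(sub), failures = n_fail,
                             truth = truth, stringsAsFactors = FALSE))
    }
    if (nrow(sub) == 0L) {
      return(metric_row("bias", NA_real_, NA_real_))
    }
    b <- estimate_bias(sub$estimate, truth)
    cv <- estimate_coverage(sub$ci_lower, sub$ci_upper, truth)
    out <- rbind(metric_row("bias", as.numeric(b), attr(b, "mc_se")),
                 metric_row("coverage", as.numeric(cv), attr(cv, "mc_se")))
    if (!is.null(res$mse)) {
      ms <- res$mse[res$mse$method == m & res$mse$converged, , drop = FALSE]
      if (nrow(ms)) {
        out <- rbind(out, metric_row(
          "mse", mean(ms$mse), stats::sd(ms$mse) / sqrt(nrow(ms))))
      }
    }
    out
  })
  do.call(rbind, rows)
}
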