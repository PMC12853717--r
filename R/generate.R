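#' Draw covariates from a model specification
#'
#' Draws `n` rows of covariates. Under setting S4 the designated pair is
#' coupled through the Gaussian copula at the spec's target Pearson
#' correlation (margins unchanged); all other covariates are mutually
#' independent.
#'
#' @param spec A [model1_spec()] or [model2_spec()].
#' @param n Number of rows.
#' @return Data frame of covariates (no outcome).
#' @export
generate_covariates <- function(spec, n) {
  dists <- spec$covariate_dists
  out <- vector("list", length(dists))
  names(out) <- names(dists)
  if (!is.null(spec$correlation)) {
    pr <- spec$correlation$pair
    pair <- draw_correlated_pair(dists[[pr[1]]], dists[[pr[2]]],
                                 spec$correlation$rho, n)
    out[[pr[1]]] <- pair$a
    out[[pr[2]]] <- pair$b
  }
  for (nm in names(dists)) {
    if (is.null(out[[nm]])) out[[nm]] <- dist_draw(dists[[nm]], n)
  }
  as.data.frame(out)
}

# Noise-free linear predictor (includes the S5 quadratic term).
linear_predictor <- function(spec, covariates) {
  eta <- rep(spec$intercept, nrow(covariates))
  for (nm in names(spec$coefs)) {
    eta <- eta + spec$coefs[[nm]] * covariates[[nm]]
  }
  if (!is.null(spec$quad_coef)) {
    nm <- names(spec$quad_coef)
    eta <- eta + spec$quad_coef[[nm]] * covariates[[nm]]^2
  }
  eta
}

#' Simulation scenario configuration
#'
#' One cell of the simulation grid: a data-generating model with calibrated
#' residual SD, a sample size, a target below-LLOQ proportion, a target
#' adjusted R-squared, a replication count and a root seed. Grid values are
#' checked against the study design (`n` in 30..1000, proportions 0.01 and
#' 0.05..0.95 in steps of 0.05, R-squared 0.1 or 0.6) unless
#' `allow_custom = TRUE`.
#'
#' @param spec A [model1_spec()] or [model2_spec()] with `sigma` set (see
#'   [calibrate_sigma()]).
#' @param n Sample size per replicate.
#' @param lloq_proportion Target below-LLOQ proportion.
#' @param target_r2 Adjusted R-squared the spec's sigma was calibrated to.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Root seed; each replicate derives its own stream from it.
#' @param lloq Censoring threshold. Defaults to the theoretical quantile of
#'   the BLOQ variable's generating distribution (Model 1) or the
#'   Monte-Carlo outcome quantile (Model 2), so the threshold is one fixed
#'   number for all replicates of the scenario.
#' @param allow_custom Accept grid values outside the study design.
#'
#' @return A `bloq_scenario` list.
#' @export
scenario_config <- function(spec, n, lloq_proportion, target_r2, reps, seed,
                            lloq = NULL, allow_custom = FALSE) {
  stopifnot(inherits(spec, "bloq_model_spec"))
  if (is.na(spec$sigma)) stop("spec$sigma is not calibrated")
  if (!allow_custom) {
    if (!n %in% supported_n) stop("unsupported n: ", n)
    if (!any(abs(lloq_proportion - supported_proportions) < 1e-9)) {
      stop("unsupported lloq_proportion: ", lloq_proportion)
    }
    if (!target_r2 %in% supported_r2) stop("unsupported target_r2: ", target_r2)
  }
  if (is.null(lloq)) {
    lloq <- if (spec$role == "independent") {
      lloq_for_proportion(spec$covariate_dists[[spec$bloq_var]],
                          lloq_proportion)
    } else {
      outcome_lloq(spec, lloq_proportion)
    }
  }
  structure(list(spec = spec, n = as.integer(n),
                 lloq_proportion = lloq_proportion, target_r2 = target_r2,
                 reps = as.integer(reps), seed = as.integer(seed),
                 lloq = lloq),
            class = "bloq_scenario")
}

#' @export
print.bloq_scenario <- function(x, ...) {
  cat(sprintf(
    "<bloq_scenario> Model %d %s | n = %d, BLOQ prop = %g, R2 = %g, reps = %d, LLOQ = %.4g, seed = %d\n",
    x$spec$model_id, x$spec$setting, x$n, x$lloq_proportion, x$target_r2,
    x$reps, x$lloq, x$seed))
  invisible(x)
}

# Counter-based per-replicate seed: replicates are independent streams and
# individually re-runnable. Exact in double arithmetic (< 2^53) and bounded
# below 2^31 for set.seed().
rep_seed <- function(seed, rep_index) {
  as.integer((as.numeric(seed) %% 2147483647 * 1000003 +
                as.numeric(rep_index) * 10007) %% 2147483629) + 1L
}

#' Generate one replicate dataset
#'
#' Draws covariates per the scenario's model spec (copula-coupled pair under
#' S4), forms the outcome as linear predictor (plus the S5 quadratic term)
#' plus `Normal(0, sigma)` noise, and returns the clean (uncensored) data.
#' Deterministic given `(cfg$seed, rep_index)`.
#'
#' @param cfg A [scenario_config()].
#' @param rep_index Replicate counter (1-based).
#' @return Data frame of covariates and outcome `y`.
#' @export
generate_dataset <- function(cfg, rep_index = 1L) {
  stopifnot(inherits(cfg, "bloq_scenario"))
  spec <- cfg$spec
  with_local_seed(rep_seed(cfg$seed, rep_index), {
    d <- generate_covariates(spec, cfg$n)
    d$y <- linear_predictor(spec, d) + stats::rnorm(cfg$n, 0, spec$sigma)
    d
  })
}

#' Censor a replicate's BLOQ variable at the scenario threshold
#'
#' Applies the scenario's fixed LLOQ to the dataset's BLOQ variable,
#' replacing censored entries by the sentinel and adding the companion
#' logical column `"<bloq_var>_censored"`.
#'
#' @param data Clean data frame from [generate_dataset()].
#' @param cfg The [scenario_config()].
#' @return The data frame with the BLOQ column censored and flagged.
#' @export
censor_dataset <- function(data, cfg) {
  cv <- apply_lloq(data[[cfg$spec$bloq_var]], cfg$lloq)
  data[[cfg$spec$bloq_var]] <- cv$values
  data[[paste0(cfg$spec$bloq_var, "_censored")]] <- cv$censored
  data
}
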