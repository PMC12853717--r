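#' Run all replicates of one simulation scenario
#'
#' For each replicate: generate a clean dataset, censor the BLOQ variable at
#' the scenario's fixed LLOQ, apply every requested method, and collect the
#' fitted coefficients with standard errors and confidence limits. Failures
#' (e.g. too few uncensored rows for the discard method at extreme
#' censoring) are recorded per replicate and never abort the scenario.
#'
#' @param cfg A [scenario_config()].
#' @param methods Character vector of method tags (see [bloq_methods()]).
#'   Every method must be applicable to the scenario's BLOQ role; an
#'   inapplicable method is rejected before any replicate runs.
#' @param pop Optional population from [generate_population()]; required
#'   when `compute_mse = TRUE`.
#' @param compute_mse Also compute the population mean squared prediction
#'   error of every successful fit (censored-covariate scenarios only).
#' @param k,fill Passed to [fit_method()].
#'
#' @return A list of class `bloq_scenario_results`:
#'   `fits` — data frame, one row per (method, replicate, coefficient) with
#'   scenario identifiers, `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `sigma_hat`, `n_used`, `converged` and `is_target`;
#'   `failures` — data frame of (method, rep, error);
#'   `mse` — data frame of (method, rep, mse) when requested;
#'   `cfg` — the configuration.
#' @export
run_scenario <- function(cfg, methods, pop = NULL, compute_mse = FALSE,
                         k = 5L, fill = 0) {
  stopifnot(inherits(cfg, "bloq_scenario"))
  spec <- cfg$spec
  for (m in methods) check_applicable(m, spec$role)
  if (compute_mse && spec$role == "dependent") {
    stop("MSE not defined for censored-outcome scenarios")
  }
  if (compute_mse && is.null(pop)) stop("`pop` required when compute_mse = TRUE")

  target_term <- function(method) {
    if (spec$role == "dependent") spec$target_coef
    else if (method == "two_compartment") paste0(spec$bloq_var, "_cont")
    else spec$bloq_var
  }

  fit_rows <- vector("list", cfg$reps * length(methods))
  mse_rows <- vector("list", if (compute_mse) cfg$reps * length(methods) else 0L)
  fail_rows <- list()
  slot <- 0L

  for (r in seq_len(cfg$reps)) {
    d <- censor_dataset(generate_dataset(cfg, r), cfg)
    for (m in methods) {
      slot <- slot + 1L
      res <- tryCatch(
        fit_method(d, role = spec$role, method = m, formula = spec$formula,
                   bloq_var = spec$bloq_var, lloq = cfg$lloq,
                   k = k, fill = fill),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        fail_rows[[length(fail_rows) + 1L]] <- data.frame(
          method = m, rep = r, error = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      terms_ <- names(res$coef)
      fit_rows[[slot]] <- data.frame(
        model_id = spec$model_id, setting = spec$setting, n = cfg$n,
        lloq_proportion = cfg$lloq_proportion, target_r2 = cfg$target_r2,
        method = m, rep = r, term = terms_,
        estimate = unname(res$coef), se = unname(res$se),
        ci_lower = unname(res$ci_lower), ci_upper = unname(res$ci_upper),
        sigma_hat = res$sigma_hat, n_used = res$n_used,
        converged = res$converged, is_target = terms_ == target_term(m),
        stringsAsFactors = FALSE)
      if (compute_mse) {
        mse_rows[[slot]] <- data.frame(
          method = m, rep = r,
          mse = mse_population(res, pop, cfg),
          converged = res$converged, stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(
    fits = do.call(rbind, fit_rows[!vapply(fit_rows, is.null, logical(1))]),
    failures = if (length(fail_rows)) do.call(rbind, fail_rows) else
      data.frame(method = character(), rep = integer(), error = character()),
    mse = if (compute_mse) {
      do.call(rbind, mse_rows[!vapply(mse_rows, is.null, logical(1))])
    } else NULL,
    cfg = cfg
  ), class = "bloq_scenario_results")
}

#' @export
print.bloq_scenario_results <- function(x, ...) {
  print(x$cfg)
  cat(sprintf("  %d fit rows, %d failures%s\n", nrow(x$fits), nrow(x$failures),
              if (!is.null(x$mse)) sprintf(", %d MSE values", nrow(x$mse))
              else ""))
  invisible(x)
}
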