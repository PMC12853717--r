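#' @title Uniform fit results
#' @description Constructor for the common result object returned by every
#'   BLOQ-handling method: coefficients, standard errors, confidence limits,
#'   the residual scale estimate, the number of observations used, and a
#'   convergence flag.
#' @keywords internal
new_bloq_fit <- function(coef, se, ci_lower, ci_upper, sigma_hat, n_used,
                         converged, method, diagnostics = list()) {
  stopifnot(length(se) == length(coef), length(ci_lower) == length(coef))
  structure(
    list(coef = coef, se = se, ci_lower = ci_lower, ci_upper = ci_upper,
         sigma_hat = sigma_hat, n_used = as.integer(n_used),
         converged = isTRUE(converged), method = method,
         diagnostics = diagnostics),
    class = "bloq_fit"
  )
}

#' @export
print.bloq_fit <- function(x, ...) {
  cat(sprintf("<bloq_fit> method = %s, n_used = %d, converged = %s\n",
              x$method, x$n_used, x$converged))
  tab <- data.frame(estimate = x$coef, se = x$se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(round(tab, 4))
  cat(sprintf("sigma_hat = %.4f\n", x$sigma_hat))
  invisible(x)
}

#' @export
coef.bloq_fit <- function(object, ...) object$coef

# OLS backbone shared by every completed-data method: t-based intervals.
# A rank-deficient design (e.g. a completed covariate that went constant)
# yields NA coefficients; such fits are flagged non-converged rather than
# silently reported.
fit_ols <- function(formula, data, method, conf_level = 0.95) {
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  est <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"][names(est)]
  names(se) <- names(est)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  new_bloq_fit(
    coef = est, se = se,
    ci_lower = est - tq * se, ci_upper = est + tq * se,
    sigma_hat = sm$sigma, n_used = stats::nobs(fit),
    converged = !anyNA(est) && !anyNA(se),
    method = method, diagnostics = list(df_residual = fit$df.residual)
  )
}

#' Complete-case (discard) fit
#'
#' Drops every row whose BLOQ variable is censored and fits the regression
#' by ordinary least squares on the remaining rows.
#'
#' @param data Data frame with the model variables and the logical column
#'   `"<bloq_var>_censored"`.
#' @param formula Model formula.
#' @param bloq_var Name of the left-censored variable.
#' @param conf_level Confidence level for the t-based intervals.
#'
#' @return A `bloq_fit`; `n_used` equals the number of uncensored rows.
#' @export
fit_discard <- function(data, formula, bloq_var, conf_level = 0.95) {
  flag <- as.logical(data[[paste0(bloq_var, "_censored")]])
  if (is.null(flag)) stop("missing censoring flag column for ", bloq_var)
  keep <- !flag
  p <- length(attr(stats::terms(formula), "term.labels")) + 1L
  if (sum(keep) < p + 2L) {
    stop(sprintf("insufficient data: %d uncensored rows for %d coefficients",
                 sum(keep), p))
  }
  fit <- fit_ols(formula, data[keep, , drop = FALSE], "discard", conf_level)
  fit$diagnostics$n_dropped <- sum(!keep)
  fit
}

#' Applicability of each BLOQ-handling method
#'
#' The tobit model is only defined when the censored variable is the
#' regression outcome (the censoring enters its likelihood through the
#' outcome); the two-compartment design only when it is a covariate (it
#' rewrites the design matrix). All other methods apply to either role.
#'
#' @return Data frame with columns `method` and `applicability`
#'   (`"independent"`, `"dependent"` or `"both"`).
#' @export
bloq_methods <- function() {
  data.frame(
    method = c("discard", "sub_zero", "sub_lloq", "sub_half", "sub_sqrt2",
               "tobit", "knn", "kde", "two_compartment"),
    applicability = c("both", "both", "both", "both", "both",
                      "dependent", "both", "both", "independent"),
    stringsAsFactors = FALSE
  )
}

check_applicable <- function(method, role) {
  tab <- bloq_methods()
  appl <- tab$applicability[match(method, tab$method)]
  if (is.na(appl)) stop("unknown method: ", method)
  if (appl != "both" && appl != role) {
    stop(sprintf(
      "method/role mismatch: '%s' is only applicable when the BLOQ variable is the %s variable",
      method, appl))
  }
  invisible(TRUE)
}

#' Fit a regression handling below-LLOQ values by a chosen method
#'
#' One entry point for all eight BLOQ-handling strategies. Completion-based
#' methods (substitution, kNN, KDE, two-compartment) first complete the
#' censored variable and then fit ordinary least squares; `"discard"` drops
#' censored rows; `"tobit"` maximises the censored likelihood directly. The
#' applicability matrix is enforced: `"tobit"` requires
#' `role = "dependent"`, `"two_compartment"` requires
#' `role = "independent"`.
#'
#' @param data Data frame with the model variables, the BLOQ variable, and
#'   its logical companion column `"<bloq_var>_censored"`. Censored slots of
#'   the BLOQ column must hold the sentinel `lloq`.
#' @param role `"independent"` if the BLOQ variable is a covariate,
#'   `"dependent"` if it is the outcome.
#' @param method One of the tags in [bloq_methods()].
#' @param formula Model formula (e.g. `y ~ age + sexmale + crp`).
#' @param bloq_var Name of the left-censored variable.
#' @param lloq Positive censoring threshold.
#' @param k Donor count for `"knn"`.
#' @param fill Fill constant for `"two_compartment"` (in `[0, lloq]`).
#' @param conf_level Confidence level (0.95 throughout the simulation
#'   study).
#' @param ... Further arguments passed to [impute_kde()].
#'
#' @return A `bloq_fit`. The attribute `"completion"` records how censored
#'   entries were completed (rule constants, kNN donor pool, KDE constant,
#'   two-compartment fill, and the completed values), so the same rule can
#'   be replayed on new data — e.g. by [mse_population()]. For
#'   `method = "two_compartment"` the coefficient of interest is the one on
#'   `"<bloq_var>_cont"` (see attribute `"target_term"`).
#' @export
fit_method <- function(data, role = c("independent", "dependent"), method,
                       formula, bloq_var, lloq, k = 5L, fill = 0,
                       conf_level = 0.95, ...) {
  role <- match.arg(role)
  check_applicable(method, role)
  flag_col <- paste0(bloq_var, "_censored")
  if (is.null(data[[flag_col]])) {
    stop("missing censoring flag column: ", flag_col)
  }
  flag <- as.logical(data[[flag_col]])
  cv <- censored_vector(replace(data[[bloq_var]], flag, lloq), flag, lloq)

  rhs_vars <- attr(stats::terms(formula), "term.labels")
  completion <- list(method = method, lloq = lloq, bloq_var = bloq_var)
  target_term <- if (role == "independent") bloq_var else NULL

  if (method == "discard") {
    fit <- fit_discard(data, formula, bloq_var, conf_level)
  } else if (method %in% c("sub_zero", "sub_lloq", "sub_half", "sub_sqrt2")) {
    rule <- sub("^sub_", "", method)
    data[[bloq_var]] <- substitute_bloq(cv, rule)
    completion$constant <- substitution_value(lloq, rule)
    fit <- fit_ols(formula, data, method, conf_level)
  } else if (method == "tobit") {
    X <- stats::model.matrix(stats::reformulate(rhs_vars), data)
    fit <- fit_tobit(cv, X, conf_level = conf_level)
  } else if (method == "knn") {
    covars <- setdiff(rhs_vars, bloq_var)
    if (role == "dependent") {
      covars <- rhs_vars
    }
    data[[bloq_var]] <- impute_knn(data, bloq_var, covars, lloq, k = k)
    completion$knn <- knn_completion_state(data, bloq_var, covars, flag, k)
    fit <- fit_ols(formula, data, method, conf_level)
  } else if (method == "kde") {
    kj <- impute_kde(cv, ...)
    data[[bloq_var]] <- replace(cv$values, cv$censored, as.numeric(kj))
    completion$constant <- as.numeric(kj)
    completion$kde_iterations <- attr(kj, "iterations")
    fit <- fit_ols(formula, data, method, conf_level)
  } else if (method == "two_compartment") {
    tc <- two_compartment_design(cv, fill)
    bin_col <- paste0(bloq_var, "_bin")
    cont_col <- paste0(bloq_var, "_cont")
    data[[bin_col]] <- tc$x_bin
    data[[cont_col]] <- tc$x_cont
    new_rhs <- c(setdiff(rhs_vars, bloq_var), cont_col)
    # with zero censored rows the indicator is constant: drop it to keep
    # the design full rank
    bin_dropped <- !any(cv$censored)
    if (!bin_dropped) new_rhs <- c(new_rhs, bin_col)
    lhs <- deparse(formula[[2L]])
    fit <- fit_ols(stats::reformulate(new_rhs, response = lhs), data,
                   "two_compartment", conf_level)
    completion$fill <- fill
    completion$bin_dropped <- bin_dropped
    target_term <- cont_col
  } else {
    stop("unknown method: ", method)
  }

  completion$values <- data[[bloq_var]]
  attr(fit, "completion") <- completion
  attr(fit, "target_term") <- target_term
  fit
}

# Everything needed to replay the training-time kNN rule on new data:
# standardisation parameters from the training table, the donor pool
# (standardised covariates + observed values), and k.
knn_completion_state <- function(data, bloq_var, covars, flag, k) {
  covm <- as.matrix(data[covars])
  std <- standardize_columns(covm)
  donors <- which(!flag)
  list(covars = colnames(covm)[std$keep], mean = std$mean, sd = std$sd,
       donor_z = std$z[donors, , drop = FALSE],
       donor_values = data[[bloq_var]][donors],
       k = min(k, length(donors)))
}
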