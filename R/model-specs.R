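#' Data-generating model specifications
#'
#' The simulation study uses two linear data-generating models.
#'
#' **Model 1** (left-censored covariate): cholesterol regressed on age, sex
#' and the inflammation biomarker CRP,
#' `y = 40 + 3*age - 1.5*sexmale + 5*crp + e`, with
#' `age ~ Normal(53, sd 4.17)`, `sexmale ~ Bernoulli(0.6)`,
#' `crp ~ Beta(a, b)` and `e ~ Normal(0, sigma)`. CRP is the BLOQ variable.
#'
#' **Model 2** (left-censored outcome): a treatment-effect model
#' `y = 2*treat - 0.5*x1 + 3*x2 + e`, with `treat ~ Bernoulli(0.6)`,
#' `x1 ~ Normal(2, sd 2)`, `x2 ~ Beta(a, b)`; the outcome y is the BLOQ
#' variable. No intercept is generated; fitted models always include one.
#'
#' Five settings vary the shape of the beta-distributed variable and the
#' dependence/linearity structure:
#' \describe{
#'   \item{S1}{right-skewed `Beta(8, 2)`, independent covariates, linear}
#'   \item{S2}{left-skewed `Beta(2, 8)`, independent covariates, linear}
#'   \item{S3}{centred `Beta(5, 5)`, independent covariates, linear}
#'   \item{S4}{as S1 plus correlation — Pearson 0.8 between crp and age
#'     (Model 1) or 0.6 between treat and x1 (Model 2)}
#'   \item{S5}{Model 1 only: as S1 but with a non-linear CRP effect,
#'     `y = 40 + 3*age - 1.5*sexmale + 3*crp + crp^2 + e`}
#' }
#'
#' @param setting One of `"S1"`..`"S5"` (`"S5"` only for Model 1).
#' @param sigma Residual standard deviation; usually left `NA` and filled in
#'   by [calibrate_sigma()].
#'
#' @return A `bloq_model_spec` list with fields `model_id`, `setting`,
#'   `intercept`, `coefs`, `quad_coef` (S5 only), `covariate_dists`,
#'   `correlation`, `nonlinear`, `sigma`, `bloq_var`, `role`, `formula` and
#'   `target_coef` (the coefficient tracked by the performance metrics:
#'   crp in Model 1, treat in Model 2).
#' @examples
#' model1_spec("S1")
#' model2_spec("S4")
#' @name model_specs
NULL

beta_for_setting <- function(setting) {
  switch(setting,
    S1 = dist_beta(8, 2),   # right skewed
    S2 = dist_beta(2, 8),   # left skewed
    S3 = dist_beta(5, 5),   # centred
    S4 = dist_beta(8, 2),   # right skewed, with correlation
    S5 = dist_beta(8, 2),   # right skewed, non-linear effect
    stop("unknown setting: ", setting)
  )
}

#' @rdname model_specs
#' @export
model1_spec <- function(setting = c("S1", "S2", "S3", "S4", "S5"),
                        sigma = NA_real_) {
  setting <- match.arg(setting)
  nonlinear <- setting == "S5"
  structure(list(
    model_id = 1L,
    setting = setting,
    intercept = 40,
    coefs = c(age = 3, sexmale = -1.5,
              crp = if (nonlinear) 3 else 5),
    quad_coef = if (nonlinear) c(crp = 1) else NULL,
    covariate_dists = list(
      age = dist_normal(53, 4.17),
      sexmale = dist_bernoulli(0.6),
      crp = beta_for_setting(setting)
    ),
    correlation = if (setting == "S4") {
      list(pair = c("crp", "age"), rho = 0.8)
    } else NULL,
    nonlinear = nonlinear,
    sigma = sigma,
    bloq_var = "crp",
    role = "independent",
    formula = y ~ age + sexmale + crp,
    target_coef = "crp"
  ), class = "bloq_model_spec")
}

#' @rdname model_specs
#' @export
model2_spec <- function(setting = c("S1", "S2", "S3", "S4"),
                        sigma = NA_real_) {
  setting <- match.arg(setting)
  structure(list(
    model_id = 2L,
    setting = setting,
    intercept = 0,
    coefs = c(treat = 2, x1 = -0.5, x2 = 3),
    quad_coef = NULL,
    covariate_dists = list(
      treat = dist_bernoulli(0.6),
      x1 = dist_normal(2, 2),
      x2 = beta_for_setting(setting)
    ),
    correlation = if (setting == "S4") {
      list(pair = c("treat", "x1"), rho = 0.6)
    } else NULL,
    nonlinear = FALSE,
    sigma = sigma,
    bloq_var = "y",
    role = "dependent",
    formula = y ~ treat + x1 + x2,
    target_coef = "treat"
  ), class = "bloq_model_spec")
}

#' @export
print.bloq_model_spec <- function(x, ...) {
  cat(sprintf("<bloq_model_spec> Model %d, setting %s (BLOQ variable: %s, %s)\n",
              x$model_id, x$setting, x$bloq_var, x$role))
  cat("  coefficients:", paste(names(x$coefs), x$coefs, sep = " = ",
                               collapse = ", "),
      sprintf("(intercept %g)", x$intercept), "\n")
  if (!is.null(x$quad_coef)) {
    cat("  quadratic term:", names(x$quad_coef), "^2 *", x$quad_coef, "\n")
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("  correlation: rho(%s, %s) = %g\n",
                x$correlation$pair[1], x$correlation$pair[2],
                x$correlation$rho))
  }
  cat(sprintf("  sigma: %s\n",
              if (is.na(x$sigma)) "not calibrated" else format(x$sigma)))
  invisible(x)
}

# grids supported by the study design
supported_n <- c(30L, 45L, 60L, 100L, 200L, 300L, 400L, 500L, 1000L)
supported_proportions <- c(0.01, seq(0.05, 0.95, by = 0.05))
supported_r2 <- c(0.1, 0.6)
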