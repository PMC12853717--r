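#' Tobit (left-censored maximum likelihood) regression
#'
#' Fits the linear model `y* = X b + e`, `e ~ N(0, sigma^2)`, when the
#' outcome is only observed above a known censoring limit `c` (the LLOQ):
#' observations with `y* <= c` contribute the normal CDF term
#' `log Phi((c - x'b)/sigma)` to the log-likelihood, uncensored observations
#' the usual normal density term. The likelihood is maximised over
#' `(b, log sigma)` by BFGS with analytic gradient, started at the OLS fit
#' of the censored-as-LLOQ outcome; standard errors come from the observed
#' information (numerical Hessian at the optimum) and confidence intervals
#' are Wald (normal-quantile) intervals.
#'
#' @param y A [censored_vector()] outcome (censoring limit = its `lloq`), or
#'   a numeric vector accompanied by `censored`.
#' @param X Design matrix (including the intercept column), full column
#'   rank, one row per observation.
#' @param censored Logical vector, required when `y` is a plain numeric
#'   vector.
#' @param lloq Censoring limit, required when `y` is a plain numeric vector.
#' @param conf_level Confidence level for the Wald intervals.
#'
#' @return A `bloq_fit` object (see [fit_method()]) with `coef`, `se`,
#'   `ci_lower`, `ci_upper`, `sigma_hat`, `n_used`, `converged`.
#' @export
fit_tobit <- function(y, X, censored = NULL, lloq = NULL, conf_level = 0.95) {
  if (inherits(y, "censored_vector")) {
    censored <- y$censored
    lloq <- y$lloq
    y <- y$values
  }
  stopifnot(is.numeric(y), is.logical(censored), length(y) == length(censored),
            is.numeric(lloq), length(lloq) == 1L)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (all(censored)) stop("likelihood unidentified: all observations censored")

  unc <- !censored
  yu <- y[unc]
  Xu <- X[unc, , drop = FALSE]
  Xc <- X[censored, , drop = FALSE]
  p <- ncol(X)

  nll <- function(par) {
    b <- par[seq_len(p)]
    sig <- exp(par[p + 1L])
    ll <- sum(stats::dnorm((yu - Xu %*% b) / sig, log = TRUE)) -
      length(yu) * log(sig)
    if (nrow(Xc)) {
      ll <- ll + sum(stats::pnorm((lloq - Xc %*% b) / sig, log.p = TRUE))
    }
    -ll
  }
  gr <- function(par) {
    b <- par[seq_len(p)]
    sig <- exp(par[p + 1L])
    r <- (yu - Xu %*% b) / sig
    gb <- crossprod(Xu, r) / sig
    gs <- sum(r^2) - length(yu)
    if (nrow(Xc)) {
      z <- (lloq - Xc %*% b) / sig
      lam <- exp(stats::dnorm(z, log = TRUE) -
                   stats::pnorm(z, log.p = TRUE))  # inverse Mills ratio
      gb <- gb - crossprod(Xc, lam) / sig
      gs <- gs - sum(lam * z)
    }
    -c(gb, gs)
  }

  start_fit <- stats::lm.fit(X, replace(y, censored, lloq))
  sig0 <- stats::sd(start_fit$residuals)
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- stats::sd(y) + 1e-8
  start <- c(start_fit$coefficients, log(sig0))

  opt <- stats::optim(start, nll, gr, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500L))
  est <- opt$par[seq_len(p)]
  names(est) <- colnames(X)
  sigma_hat <- unname(exp(opt$par[p + 1L]))

  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  converged <- opt$convergence == 0L && !is.null(vc) &&
    all(diag(vc)[seq_len(p)] > 0)
  se <- if (is.null(vc)) rep(NA_real_, p) else sqrt(pmax(diag(vc)[seq_len(p)], 0))
  names(se) <- colnames(X)

  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  new_bloq_fit(
    coef = est, se = se,
    ci_lower = est - zq * se, ci_upper = est + zq * se,
    sigma_hat = sigma_hat, n_used = length(y), converged = converged,
    method = "tobit",
    diagnostics = list(optim_convergence = opt$convergence,
                       neg_loglik = opt$value, n_censored = sum(censored))
  )
}
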