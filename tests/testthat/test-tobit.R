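test_that("tobit reduces to OLS when nothing is censored", {
  set.seed(31)
  n <- 300
  x <- rnorm(n)
  y <- 10 + 2 * x + rnorm(n)
  cv <- censored_vector(y, rep(FALSE, n), max(min(y) / 2, 1e-9))
  X <- cbind("(Intercept)" = 1, x = x)
  ft <- fit_tobit(cv, X)
  ols <- coef(lm(y ~ x))
  expect_true(ft$converged)
  expect_equal(unname(ft$coef), unname(ols), tolerance = 1e-6)
  # MLE scale is the sqrt(n) denominator version of the OLS sigma
  expect_equal(ft$sigma_hat, sqrt(sum(residuals(lm(y ~ x))^2) / n),
               tolerance = 1e-5)
})

test_that("tobit recovers generating coefficients under 30% censoring", {
  set.seed(32)
  n <- 5000
  x <- rnorm(n)
  y <- 10 + 2 * x + rnorm(n)
  cv <- apply_lloq(y, unname(quantile(y, 0.3)))
  ft <- fit_tobit(cv, cbind("(Intercept)" = 1, x = x))
  expect_true(ft$converged)
  # within 3 standard errors of the truth
  expect_lt(abs(ft$coef[["(Intercept)"]] - 10), 3 * ft$se[["(Intercept)"]])
  expect_lt(abs(ft$coef[["x"]] - 2), 3 * ft$se[["x"]])
  expect_equal(ft$sigma_hat, 1, tolerance = 0.05)
})

test_that("the returned estimate is a local maximum of the log-likelihood", {
  set.seed(33)
  n <- 200
  x <- rnorm(n)
  y <- 5 + 1.5 * x + rnorm(n)
  cv <- apply_lloq(y, unname(quantile(y, 0.25)))
  X <- cbind("(Intercept)" = 1, x = x)
  ft <- fit_tobit(cv, X)
  loglik <- function(b, sig) {
    unc <- !cv$censored
    sum(dnorm(cv$values[unc], X[unc, ] %*% b, sig, log = TRUE)) +
      sum(pnorm((cv$lloq - X[cv$censored, ] %*% b) / sig, log.p = TRUE))
  }
  at_opt <- loglik(ft$coef, ft$sigma_hat)
  for (j in 1:2) for (d in c(-0.01, 0.01)) {
    b <- ft$coef
    b[j] <- b[j] + d
    expect_gte(at_opt, loglik(b, ft$sigma_hat))
  }
})

test_that("tobit agrees with the survreg left-censored gaussian fit", {
  skip_if_not_installed("survival")
  set.seed(34)
  n <- 1500
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  y <- 8 + 1.2 * x1 - 0.7 * x2 + rnorm(n, 0, 1.5)
  cv <- apply_lloq(y, unname(quantile(y, 0.4)))
  ft <- fit_tobit(cv, cbind("(Intercept)" = 1, x1 = x1, x2 = x2))
  sr <- survival::survreg(
    survival::Surv(cv$values, !cv$censored, type = "left") ~ x1 + x2,
    dist = "gaussian")
  expect_equal(unname(ft$coef), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(ft$sigma_hat, sr$scale, tolerance = 1e-3)
  expect_equal(unname(ft$se), unname(sqrt(diag(vcov(sr))[1:3])),
               tolerance = 1e-3)
})

test_that("tobit estimation error shrinks with sample size", {
  err_at <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    y <- 10 + 2 * x + rnorm(n)
    cv <- apply_lloq(y, unname(quantile(y, 0.4)))
    ft <- fit_tobit(cv, cbind("(Intercept)" = 1, x = x))
    abs(ft$coef[["x"]] - 2)
  }
  # average over a few fixed seeds so the comparison reflects the trend
  errs <- sapply(c(200, 1000, 5000), function(n) {
    mean(sapply(1:5, function(s) err_at(n, 330 + s)))
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[2], errs[1])
})

test_that("degenerate tobit inputs are rejected", {
  y <- c(0.5, 0.5, 0.5)
  cv <- censored_vector(c(1, 1, 1), rep(TRUE, 3), 1)
  expect_error(fit_tobit(cv, cbind(1, c(1, 2, 3))), "unidentified")
  cv2 <- apply_lloq(c(2, 3, 4), 1)
  expect_error(fit_tobit(cv2, cbind(1, c(1, 1, 1))), "rank deficient")
})
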