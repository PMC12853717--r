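test_that("the applicability matrix is enforced before any fitting", {
  d <- toy_bloq_table()
  expect_error(
    fit_method(d, "independent", "tobit", y ~ age + crp, "crp", 0.6),
    "method/role mismatch")
  expect_error(
    fit_method(d, "dependent", "two_compartment", y ~ age + crp, "y", 0.6),
    "method/role mismatch")
  expect_error(
    fit_method(d, "independent", "winsorize", y ~ age + crp, "crp", 0.6),
    "unknown method")
})

test_that("substitution fits equal OLS on the substituted data", {
  d <- toy_bloq_table()
  cv <- censored_vector(d$crp, d$crp_censored, 0.6)
  d2 <- d
  d2$crp <- substitute_bloq(cv, "half")
  direct <- lm(y ~ age + sexmale + crp, d2)
  ft <- fit_method(d, "independent", "sub_half", y ~ age + sexmale + crp,
                   "crp", 0.6)
  expect_equal(ft$coef, coef(direct))
  expect_equal(unname(ft$se), unname(summary(direct)$coefficients[, 2]))
})

test_that("discard drops exactly the censored rows", {
  d <- toy_bloq_table()
  ft <- fit_method(d, "independent", "discard", y ~ age + sexmale + crp,
                   "crp", 0.6)
  expect_equal(ft$n_used, sum(!d$crp_censored))
  direct <- lm(y ~ age + sexmale + crp, d[!d$crp_censored, ])
  expect_equal(ft$coef, coef(direct))

  # with no censored rows, discard is plain OLS on everything
  d0 <- d
  d0$crp_censored <- FALSE
  d0$crp[1] <- 0.7
  d0$crp[5] <- 0.65
  ft0 <- fit_method(d0, "independent", "discard", y ~ age + sexmale + crp,
                    "crp", 0.6)
  expect_equal(ft0$coef, coef(lm(y ~ age + sexmale + crp, d0)))
})

test_that("discard refuses when too few uncensored rows remain", {
  d <- toy_bloq_table()
  d$crp_censored <- c(rep(TRUE, 6), FALSE, FALSE)
  expect_error(
    fit_method(d, "independent", "discard", y ~ age + sexmale + crp,
               "crp", 0.6),
    "insufficient data")
})

test_that("two-compartment fit reports the continuous-part coefficient as target", {
  d <- toy_bloq_table()
  ft <- fit_method(d, "independent", "two_compartment",
                   y ~ age + sexmale + crp, "crp", 0.6)
  expect_equal(attr(ft, "target_term"), "crp_cont")
  expect_true(all(c("crp_cont", "crp_bin") %in% names(ft$coef)))
  # without censored rows the indicator column is dropped
  d0 <- d
  d0$crp_censored <- FALSE
  d0$crp[c(1, 5)] <- c(0.7, 0.65)
  ft0 <- fit_method(d0, "independent", "two_compartment",
                    y ~ age + sexmale + crp, "crp", 0.6)
  expect_false("crp_bin" %in% names(ft0$coef))
})

test_that("every fit result has well-formed intervals around the estimate", {
  d <- toy_bloq_table()
  for (m in c("discard", "sub_zero", "sub_half", "knn", "two_compartment")) {
    ft <- fit_method(d, "independent", m, y ~ age + sexmale + crp,
                     "crp", 0.6)
    expect_true(all(ft$ci_lower <= ft$coef), info = m)
    expect_true(all(ft$coef <= ft$ci_upper), info = m)
    expect_true(all(ft$ci_upper - ft$ci_lower > 0), info = m)
    expect_lte(ft$n_used, nrow(d))
  }
})

test_that("tobit through the uniform interface matches OLS at zero censoring", {
  set.seed(61)
  n <- 120
  d <- data.frame(treat = rbinom(n, 1, 0.5), x1 = rnorm(n))
  d$y <- 5 + 2 * d$treat - 0.5 * d$x1 + rnorm(n)
  d$y <- d$y - min(d$y) + 1  # keep the outcome positive
  d$y_censored <- FALSE
  ft <- fit_method(d, "dependent", "tobit", y ~ treat + x1, "y",
                   lloq = min(d$y) / 2)
  expect_equal(unname(ft$coef), unname(coef(lm(y ~ treat + x1, d))),
               tolerance = 1e-6)
})
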