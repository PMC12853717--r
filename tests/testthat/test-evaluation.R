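test_that("bias and coverage follow their defining formulas", {
  b <- estimate_bias(c(4, 5, 6), 5)
  expect_equal(as.numeric(b), 0)
  expect_equal(attr(b, "mc_se"), sd(c(4, 5, 6)) / sqrt(3))
  expect_equal(as.numeric(estimate_bias(5.5, 5)), 0.5)
  expect_error(estimate_bias(numeric(0), 5), "no successful fits")

  lo <- c(rep(4, 19), 5.2)
  hi <- c(rep(6, 19), 5.4)
  cv <- estimate_coverage(lo, hi, 5)
  expect_equal(as.numeric(cv), 0.95)
  expect_equal(attr(cv, "mc_se"), sqrt(0.95 * 0.05 / 20))
  expect_equal(as.numeric(estimate_coverage(rep(-Inf, 5), rep(Inf, 5), 5)), 1)
  expect_error(estimate_coverage(numeric(0), numeric(0), 5),
               "no successful fits")
  expect_error(estimate_coverage(c(2, 3), c(1, 4), 5), "not exceed")
})

test_that("t-intervals from a correctly specified model attain nominal coverage", {
  set.seed(81)
  reps <- 1000
  hit <- logical(reps)
  n <- 40
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- 1 + 2 * x + rnorm(n)
    fit <- lm(y ~ x)
    ci <- confint(fit)["x", ]
    hit[r] <- ci[1] <= 2 && 2 <= ci[2]
  }
  expect_equal(mean(hit), 0.95, tolerance = 0.02)
})

test_that("population MSE approaches the irreducible error for the true model", {
  spec <- cached_m1_spec("S1")
  pop <- generate_population(spec, 82)
  cfg <- scenario_config(spec, 1000, 0.2, 0.6, reps = 1, seed = 83)
  d <- censor_dataset(generate_dataset(cfg, 1), cfg)
  ft <- fit_method(d, "independent", "discard", spec$formula, "crp", cfg$lloq)
  # force the generating coefficients into the fit: MSE must then be near
  # sigma^2 plus the censoring distortion of the population design, and on
  # the clean design exactly near sigma^2
  ft$coef[] <- c(40, 3, -1.5, 5)
  mse_clean <- mse_population(ft, pop, cfg, censor_population = FALSE)
  expect_equal(mse_clean, spec$sigma^2, tolerance = 0.02)
  # sanity: the fitted (not oracle) model cannot beat the irreducible error
  ft2 <- fit_method(d, "independent", "discard", spec$formula, "crp", cfg$lloq)
  expect_gte(mse_population(ft2, pop, cfg), 0.98 * spec$sigma^2)
})

test_that("population MSE is refused for censored-outcome scenarios", {
  spec <- cached_m2_spec("S1")
  cfg <- scenario_config(spec, 100, 0.4, 0.6, reps = 1, seed = 84)
  d <- censor_dataset(generate_dataset(cfg, 1), cfg)
  ft <- fit_method(d, "dependent", "tobit", spec$formula, "y", cfg$lloq)
  expect_error(mse_population(ft, d, cfg), "not defined")
})

test_that("summarize_metrics books every replicate exactly once", {
  spec <- cached_m1_spec("S1")
  cfg <- scenario_config(spec, 100, 0.2, 0.6, reps = 5, seed = 85)
  res <- run_scenario(cfg, c("discard", "sub_half", "two_compartment"))
  m <- summarize_metrics(res)
  # 3 methods x {bias, coverage}
  expect_equal(nrow(m), 6)
  expect_true(all(m$reps_effective + m$failures == cfg$reps))
  expect_true(all(m$value[m$metric == "coverage"] >= 0 &
                    m$value[m$metric == "coverage"] <= 1))
  expect_equal(unique(m$truth), 5)
  # binomial MC-SE for coverage
  cov_rows <- m[m$metric == "coverage", ]
  expect_equal(cov_rows$mc_se,
               sqrt(cov_rows$value * (1 - cov_rows$value) /
                      cov_rows$reps_effective))
})

test_that("metric curve figures are written for each model", {
  spec <- cached_m1_spec("S1")
  out <- list()
  for (p in c(0.2, 0.4)) {
    cfg <- scenario_config(spec, 100, p, 0.6, reps = 3, seed = 86)
    out[[as.character(p)]] <- run_scenario(cfg, c("discard", "sub_half"))
  }
  m <- summarize_metrics(out)
  dir <- withr::local_tempdir()
  files <- plot_metric_curves(m, "coverage", dir)
  expect_true(file.exists(file.path(dir, "model1_coverage.png")))
  expect_error(plot_metric_curves(m[0, ], "bias", dir), "empty")
})
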