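test_that("sigma calibration follows the variance-partition algebra", {
  # R2 = Var(eta) / (Var(eta) + sigma^2)  =>  sigma = sqrt(V (1-R2)/R2)
  # checked here through a degenerate one-covariate spec whose eta variance
  # is known analytically: eta = 3 * Normal(0, 1) gives Var(eta) = 9
  spec <- model1_spec("S1")
  spec$coefs <- c(age = 3)
  spec$covariate_dists <- list(age = dist_normal(0, 1))
  s06 <- calibrate_sigma(spec, 0.6, pop_seed = 71, pop_n = 4e5)
  s01 <- calibrate_sigma(spec, 0.1, pop_seed = 71, pop_n = 4e5)
  expect_equal(s06, sqrt(9 * 0.4 / 0.6), tolerance = 0.01)
  expect_equal(s01, sqrt(9 * 0.9 / 0.1), tolerance = 0.01)
  # calibrated sigma decreases in the target R2
  expect_gt(s01, s06)
})

test_that("calibrated sigma attains the target adjusted R2 on a fresh population", {
  for (r2 in c(0.6, 0.1)) {
    spec <- cached_m1_spec("S1", r2)
    pop <- generate_population(spec, seed = 72)
    fit <- summary(lm(y ~ age + sexmale + crp, pop))
    expect_lt(abs(fit$adj.r.squared - r2), 0.01)
  }
})

test_that("copula-coupled pairs hit the target correlation with intact margins", {
  set.seed(73)
  pr <- draw_correlated_pair(dist_beta(8, 2), dist_normal(53, 4.17), 0.8, 1e5)
  expect_equal(cor(pr$a, pr$b), 0.8, tolerance = 0.02)
  expect_gt(ks.test(pr$a, function(q) pbeta(q, 8, 2))$p.value, 0.01)
  expect_gt(ks.test(pr$b, function(q) pnorm(q, 53, 4.17))$p.value, 0.01)

  pr2 <- draw_correlated_pair(dist_bernoulli(0.6), dist_normal(2, 2), 0.6, 1e5)
  expect_equal(cor(pr2$a, pr2$b), 0.6, tolerance = 0.02)
  expect_equal(mean(pr2$a), 0.6, tolerance = 0.01)

  # independence at target zero
  pr0 <- draw_correlated_pair(dist_beta(8, 2), dist_normal(0, 1), 0, 1e5)
  expect_equal(attr(pr0, "latent_rho"), 0)
  expect_lt(abs(cor(pr0$a, pr0$b)), 0.02)
})

test_that("unattainable correlations for a margin pair are rejected", {
  # a Bernoulli(0.6)-normal pair cannot reach Pearson 0.95
  expect_error(
    draw_correlated_pair(dist_bernoulli(0.6), dist_normal(0, 1), 0.95, 10),
    "infeasible correlation")
})

test_that("the generator recovers its own coefficients and margins", {
  spec <- cached_m1_spec("S1")
  # large clean draw: OLS must recover (40, 3, -1.5, 5) within 3 SEs
  cfg <- scenario_config(spec, 1000L, 0.2, 0.6, reps = 1, seed = 74)
  d <- do.call(rbind, lapply(1:100, function(r) generate_dataset(cfg, r)))
  fit <- summary(lm(y ~ age + sexmale + crp, d))$coefficients
  truth <- c(40, 3, -1.5, 5)
  expect_true(all(abs(fit[, 1] - truth) < 3 * fit[, 2]))

  spec2 <- cached_m2_spec("S1")
  cfg2 <- scenario_config(spec2, 1000, 0.2, 0.6, reps = 1, seed = 75)
  d2 <- do.call(rbind, lapply(1:100, function(r) generate_dataset(cfg2, r)))
  expect_equal(mean(d2$treat), 0.6, tolerance = 0.005)

  # covariates are mutually independent outside S4
  cc <- cor(d[, c("age", "sexmale", "crp")])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
})

test_that("dataset generation is a pure function of (seed, rep_index)", {
  spec <- cached_m1_spec("S1")
  cfg <- scenario_config(spec, 100, 0.2, 0.6, reps = 2, seed = 76)
  expect_identical(generate_dataset(cfg, 1L), generate_dataset(cfg, 1L))
  expect_false(identical(generate_dataset(cfg, 1L), generate_dataset(cfg, 2L)))
})

test_that("scenario grids outside the study design are rejected unless allowed", {
  spec <- cached_m1_spec("S1")
  expect_error(scenario_config(spec, 77, 0.2, 0.6, 10, 1), "unsupported n")
  expect_error(scenario_config(spec, 100, 0.13, 0.6, 10, 1),
               "unsupported lloq_proportion")
  expect_error(scenario_config(spec, 100, 0.2, 0.5, 10, 1),
               "unsupported target_r2")
  expect_s3_class(scenario_config(spec, 77, 0.13, 0.6, 10, 1,
                                  allow_custom = TRUE), "bloq_scenario")
})

test_that("the censored-outcome threshold reproduces its target proportion", {
  spec <- cached_m2_spec("S1")
  lloq <- outcome_lloq(spec, 0.4)
  cfg <- scenario_config(spec, 1000, 0.4, 0.6, reps = 1, seed = 77)
  props <- vapply(1:30, function(r) {
    mean(generate_dataset(cfg, r)$y <= lloq)
  }, numeric(1))
  expect_equal(mean(props), 0.4, tolerance = 0.015)
})

test_that("the S5 pseudo-true coefficient behaves like a least-squares projection", {
  spec <- cached_m1_spec("S5")
  pop1 <- generate_population(spec, 78)
  pop2 <- generate_population(spec, 79)
  b1 <- pseudo_true_beta_s5(pop1)
  b2 <- pseudo_true_beta_s5(pop2)
  # a convex increasing extra term inflates the linear projection above 3
  expect_gt(b1, 3)
  # population seeds agree within Monte-Carlo error
  se1 <- summary(lm(spec$formula, pop1))$coefficients["crp", 2]
  se2 <- summary(lm(spec$formula, pop2))$coefficients["crp", 2]
  expect_lt(abs(b1 - b2), 2 * sqrt(se1^2 + se2^2))

  # with the quadratic coefficient removed the linear model is correct and
  # the projection returns the generating coefficient 3
  spec0 <- spec
  spec0$quad_coef <- c(crp = 0)
  pop0 <- generate_population(spec0, 80)
  expect_equal(pseudo_true_beta_s5(pop0), 3, tolerance = 0.05)
})
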