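# bloqreg

Multiple linear regression when one variable is left-censored at a known
lower limit of quantification (LLOQ).

Laboratory assays report concentrations below their quantification limit
only as "< LLOQ". When such a variable enters a linear regression — as a
covariate (e.g. the biomarker CRP predicting cholesterol) or as the
outcome — the handling of the censored values drives the bias of the
coefficient of interest, the coverage of its confidence interval, and
predictive accuracy. `bloqreg` implements eight established strategies
behind one interface and a Monte-Carlo engine for comparing them:

* **discard** — drop censored rows, fit OLS;
* **substitution** — replace censored values by `0`, `LLOQ`, `LLOQ/2`, or
  `LLOQ/sqrt(2)` (the mass-splitting point of a triangular density on
  `(0, LLOQ)`);
* **tobit** — censored maximum likelihood for a censored *outcome*,
  maximising
  `sum_unc [ -log s + log phi((y_i - x_i'b)/s) ] + sum_cens log Phi((L - x_i'b)/s)`;
* **kNN** — impute censored values from the `k = 5` nearest donors on
  standardised covariates, truncated at the LLOQ;
* **KDE** — iteratively impute `E(X | X < LLOQ)` under a Gaussian kernel
  density estimate (Silverman bandwidth, convergence tolerance `1e-5`);
* **two-compartment** — split a censored *covariate* into a below-limit
  indicator plus a continuous part and enter both as regressors.

The simulation engine generates data from two designs (censored covariate:
`y = 40 + 3*age - 1.5*sexmale + 5*crp + e`; censored outcome:
`y = 2*treat - 0.5*x1 + 3*x2 + e`) across five settings varying the
skewness of the beta-distributed variable, covariate correlation (via a
calibrated Gaussian copula) and linearity, with the residual SD calibrated
to a target adjusted R² and the censoring proportion controlled through
theoretical quantiles. Methods are scored by bias, 95%-interval coverage,
and mean squared prediction error on a 100,000-row population.

## A worked example

```r
library(bloqreg)

# a small censored dataset from the censored-covariate design
d <- make_fixture("model1", n = 200, proportion = 0.2, seed = 5)
lloq <- attr(d, "truth")$lloq     # 0.7022 for the right-skewed Beta(8,2)

fit <- fit_method(d, role = "independent", method = "two_compartment",
                  formula = y ~ age + sexmale + crp,
                  bloq_var = "crp", lloq = lloq)
fit
#> <bloq_fit> method = two_compartment, n_used = 200, converged = TRUE
#>             estimate      se ci_lower ci_upper
#> (Intercept)  40.5098 13.2010  14.4748  66.5448
#> age           3.0458  0.1765   2.6978   3.3938
#> sexmale      -2.2249  1.5455  -5.2729   0.8231
#> crp_cont      1.6967 11.8173 -21.6093  25.0028
#> crp_bin      -0.2411 10.1696 -20.2976  19.8155
#> sigma_hat = 10.7322
```

The generating CRP coefficient is 5; at n = 200 the biomarker's small
variance and the calibrated noise (adjusted R² 0.6 means sigma near 10)
leave the interval on `crp_cont` (the coefficient of interest for this
method) wide, and it covers the truth. Single small fits say little here —
comparing methods over many replicates is what `run_scenario()` /
`summarize_metrics()` are for:

```r
spec <- model1_spec("S1")
spec$sigma <- calibrate_sigma(spec, target_r2 = 0.6, pop_seed = 1)
cfg <- scenario_config(spec, n = 1000, lloq_proportion = 0.3,
                       target_r2 = 0.6, reps = 200, seed = 42)
res <- run_scenario(cfg, c("discard", "sub_half", "two_compartment"))
summarize_metrics(res)[, c("method", "metric", "value", "mc_se")]
#>            method   metric      value      mc_se
#> 1         discard     bias  0.3841617 0.44037681
#> 2         discard coverage  0.9350000 0.01743201
#> 3        sub_half     bias -2.5639336 0.10647884
#> 4        sub_half coverage  0.5700000 0.03500714
#> 5 two_compartment     bias  0.3907368 0.43919870
#> 6 two_compartment coverage  0.9350000 0.01743201
```

Discard and the two-compartment design stay unbiased here (bias within MC
error of zero, coverage near the nominal 0.95), while substituting
`LLOQ/2` for a right-skewed biomarker attenuates the coefficient (bias
-2.56, i.e. about half the generating effect) and drops coverage to 0.57.

A whole simulation grid is driven by a YAML config
(`inst/extdata/desk_grid.yaml` ships a desk-scale one):

```sh
Rscript inst/cli/bloqreg.R simulate --config inst/extdata/desk_grid.yaml --out results/
Rscript inst/cli/bloqreg.R fit --data data.csv --bloq-var crp --lloq 0.6 \
    --role independent --method sub_sqrt2 --formula "y ~ age + sexmale + crp"
```

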