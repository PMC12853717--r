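---
title: "Handling values below a limit of quantification in linear regression: methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling values below a limit of quantification in linear regression: methods and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloqreg)
```

## The problem

Laboratory assays have a lower limit of quantification (LLOQ): below a
known threshold, a concentration cannot be measured reliably and is
reported only as "< LLOQ". Statistically these observations are
left-censored — we know they lie at or below the threshold, but not where.
When such a variable enters a multiple linear regression, either as a
covariate (a biomarker predictor such as C-reactive protein, CRP) or as the
outcome (e.g. a treatment effect on an assay readout), the analyst has to
decide what to do with the censored values, and that decision affects the
bias of the coefficient of interest, the coverage of its confidence
interval, and predictive accuracy.

`bloqreg` implements eight established strategies behind the single entry
point `fit_method()`, plus a Monte-Carlo engine that evaluates them under
controlled data-generating conditions.

## Representation

A `censored_vector` holds the observed values, a logical censoring flag per
element, and the threshold. Two conventions are fixed package-wide:

* **Tie rule.** A value exactly equal to the LLOQ is censored
  (`value <= lloq`), matching the observation rule of the censored
  likelihood below.
* **Sentinel.** Censored slots store the LLOQ itself, never `NA`, so
  completion rules always read a defined number. Consumers must branch on
  the flag, not the value.

## The eight methods

Let $L$ denote the LLOQ and $c_i = 1$ flag a censored observation.

**Discard** drops all censored rows and fits ordinary least squares (OLS)
on the remainder. When the censored variable is a covariate independent of
the error, this subsampling is on the design only, so the coefficient
estimate stays unbiased — at the price of a smaller sample and wider
intervals. When the censored variable is the outcome, dropping low values
selects on the error term and biases the fit.

**Substitution** replaces every censored value by a constant: $0$, $L$,
$L/2$, or $L/\sqrt{2}$. $L/2$ is the mean of a uniform density on $(0, L)$;
$L/\sqrt{2}$ is the mass-splitting point of a triangular density with
increasing slope on $(0, L)$, i.e. the solution of
$\int_l^L c\,x\,dx = \tfrac12 \int_0^L c\,x\,dx$.

**Tobit regression** (`fit_tobit()`) treats a censored *outcome* by maximum
likelihood: uncensored observations contribute the normal density, censored
ones the probability of falling at or below the threshold,

$$\log L(\beta, \sigma) =
  \sum_{i\,\mathrm{unc}} \left[-\log\sigma +
      \log\phi\!\left(\frac{y_i - x_i^\top\beta}{\sigma}\right)\right] +
  \sum_{i\,\mathrm{cens}} \log\Phi\!\left(\frac{L - x_i^\top\beta}{\sigma}\right).$$

It is only defined when the censored variable is the dependent variable;
`fit_method()` enforces this.

**k-nearest neighbours** (`impute_knn()`) imputes each censored value as the
average of the censored variable over the $k$ (default 5) nearest donor
rows, with Euclidean distance on z-scored covariates (standardised with
full-table means and SDs; distance ties resolve by row order). The average
is truncated at $L$ so an imputed value never exceeds the detection limit.
One consequence worth knowing: whenever every donor value exceeds $L$ —
which is necessarily the case when the flags are derived from the threshold
itself, as in the simulation designs below — the truncated average is
exactly $L$ and kNN coincides with LLOQ-substitution. The method only
differs from substitution when donors below the threshold exist, e.g. in
user data with assay-specific flags.

**Kernel density imputation** (`impute_kde()`) estimates the distribution
of the variable by a Gaussian kernel density estimate with Silverman's
bandwidth $h = 1.06\,\hat\sigma\,m^{-1/5}$ and imputes the single value
$k_j = E_{\hat f}(X \mid X < L)$ into all censored slots, iterating:
iteration 1 uses the $m$ uncensored values; iteration $j$ re-estimates the
density from the uncensored values plus the censored slots filled with
$k_{j-1}$, until $|k_j - k_{j-1}| < 10^{-5}$. The conditional expectation
is taken over $(\max(0, \min(\text{sample}) - 3h),\, L)$ — the floor at 0
reflects that the variables handled here are nonnegative concentrations.
An alternative augmentation (`augment = "append"`: append one copy of every
past iterate instead of refilling the censored slots) is available for
sensitivity analysis, as is the bandwidth exponent.

**Two-compartment model** (`two_compartment_design()`) splits a censored
*covariate* into a below-limit indicator $x_{bin}$ and a continuous part
$x_{cont}$ (censored slots set to a fill constant in $[0, L]$, default 0)
and enters both as regressors. With the indicator in the model, the
coefficient on $x_{cont}$ — the coefficient of interest — is invariant to
the fill. When a dataset happens to contain no censored rows the indicator
is constant and is dropped before fitting to keep the design full rank.

## The simulation designs

Two data-generating models are built in:

* **Model 1 (censored covariate).** Cholesterol regressed on age, sex and
  CRP: $y = 40 + 3\,x_{age} - 1.5\,x_{sex} + 5\,x_{crp} + \varepsilon$,
  with $x_{age} \sim N(53, 4.17^2)$, $x_{sex} \sim \mathrm{Bern}(0.6)$,
  $x_{crp} \sim \mathrm{Beta}(a,b)$,
  $\varepsilon \sim N(0, \sigma^2)$. CRP is censored.
* **Model 2 (censored outcome).**
  $y = 2\,x_{treat} - 0.5\,x_1 + 3\,x_2 + \varepsilon$ with
  $x_{treat} \sim \mathrm{Bern}(0.6)$, $x_1 \sim N(2, 2^2)$,
  $x_2 \sim \mathrm{Beta}(a,b)$. The outcome is censored. No intercept is
  generated; fitted models always include one (asymptotically immaterial,
  and standard practice).

The `Normal(mean, s)` notation is read with `s` as a **standard
deviation** throughout.

Five settings vary the beta shape and structure: S1 right-skewed
$\mathrm{Beta}(8,2)$; S2 left-skewed $\mathrm{Beta}(2,8)$; S3 centred
$\mathrm{Beta}(5,5)$; S4 as S1 plus correlation (Pearson 0.8 between CRP
and age in Model 1; 0.6 between treatment and $x_1$ in Model 2); S5 (Model
1 only) replaces the CRP term by the non-linear $3\,x_{crp} + x_{crp}^2$.

### Noise calibration

The residual SD is not a free dial: `calibrate_sigma()` fixes it so the
generating model attains a target adjusted $R^2$ (0.6 or 0.1). From the
variance partition $R^2 = \mathrm{Var}(\eta) / (\mathrm{Var}(\eta) +
\sigma^2)$, with $\eta$ the noise-free linear predictor,
$\sigma = \sqrt{\mathrm{Var}(\eta)\,(1 - R^2)/R^2}$;
$\mathrm{Var}(\eta)$ is estimated once on a seeded 100,000-row population
of covariates. At that size the adjustment in adjusted $R^2$ is
negligible, and a verification OLS fit on a fresh population reproduces the
target within $\pm 0.01$ (this is asserted by the test suite).

### Correlated covariates

Setting S4 couples two covariates with different margins without altering
either margin, via a Gaussian copula (`draw_correlated_pair()`): a latent
bivariate normal is transformed by each margin's quantile map (linear for
normal, probability-integral for beta, thresholding for Bernoulli).
Because the transforms distort correlation, the latent correlation is
calibrated by monotone bisection on a seeded $10^6$-draw pilot with common
random numbers until the observed-scale Pearson correlation matches the
target within 0.002; the calibration is cached per session. Targets beyond
what the margin pair can support are rejected. The target is the Pearson
correlation on the *observed* scale — the scale on which an analyst would
measure it.

### Choosing the threshold

The censoring proportion of a scenario is controlled through the
**theoretical** quantile of the generating distribution of the censored
variable, so the LLOQ is one fixed number for all replicates (thresholds in
real studies do not move with the sample): `lloq_for_proportion()` uses the
closed-form beta/normal quantile for Model 1. The Model-2 outcome is a
binary + normal + beta mixture with no closed-form quantile, so
`outcome_lloq()` estimates it once per scenario from a dedicated seeded
Monte-Carlo sample of $10^6$ outcome draws (cached). Censoring is therefore
exact in expectation, not enforced per replicate.

### Metrics

For each scenario and method, over `reps` replicates of size `n`:

* **bias** $= \overline{\hat\beta} - \beta$ on the tracked coefficient
  (CRP in Model 1 — for the two-compartment fit, the coefficient on
  $x_{cont}$; treatment in Model 2);
* **coverage** = fraction of 95% confidence intervals containing $\beta$
  (t-intervals for all OLS-type fits, Wald normal intervals for tobit);
* **population MSE** (Model 1 only)
  $= \tfrac1N \sum_i (\hat y_i - y_i)^2$ on a fixed 100,000-row population
  drawn from the same generating mechanism.

Under S5 every method fits a misspecified linear model, so the "true"
$\beta$ is defined as the **population least-squares projection**: the CRP
coefficient of an OLS fit of the linear analysis model on the 100,000-row
population (`pseudo_true_beta_s5()`).

Two evaluation details are genuinely open design choices and are resolved
as follows. First, the population on which the MSE is computed is itself
subject to the detection limit, so the population design is built by
replaying each method's *training-time* completion rule on a censored copy
of the population (substitution constants, the training kNN donor pool,
the training KDE constant, the two-compartment fill). The discard method
learns no completion rule; its predictions use the censored value as
stored, i.e. substituted at the LLOQ — a choice that affects only the
discard MSE curve and can be switched off wholesale with
`censor_population = FALSE`, which predicts from the clean covariate.
Second, non-converged fits are excluded from metric numerators and
denominators but always counted: every scenario cell satisfies
`reps_effective + failures = reps`.

## Numerical choices

* **Tobit optimisation** maximises over $(\beta, \log\sigma)$ (keeping
  $\sigma > 0$) by BFGS with analytic gradient, started at the OLS fit of
  the censored-as-LLOQ outcome; standard errors come from the numerically
  evaluated observed information at the optimum. Non-convergence or a
  non-invertible Hessian is reported through `converged = FALSE`, never as
  a silent answer. With zero censored observations the censored sum is
  empty and the optimum is the OLS fit, which the tests assert to
  $10^{-6}$.
* **KDE integrals.** Both integrals defining
  $E_{\hat f}(X \mid X < L)$ are sums of Gaussian-kernel integrals with
  closed forms (differences of normal CDF/PDF values), and the default
  evaluates them analytically. A 2048-point trapezoid grid on the same
  interval is retained (`integration = "grid"`); the two routes agree to
  quadrature accuracy and the grid route doubles as an independent
  cross-check in the tests.
* **Seeding.** Each scenario has one root seed; per-replicate streams are
  derived by a counter-based map, so any replicate can be regenerated in
  isolation and a whole scenario is a pure function of its configuration.
  Session-level caches (copula calibration, Monte-Carlo outcome quantiles,
  the S5 pseudo-true coefficient) are keyed by their defining parameters
  and seeded independently of the caller's RNG stream.
* **Degenerate inputs.** All-censored tobit, zero-donor kNN, a KDE sample
  with no density mass below the threshold, and too few uncensored rows
  for discard are signalled as errors with descriptive messages; inside
  `run_scenario()` such failures are recorded per replicate and never
  abort a scenario.

## What the generator does and does not emulate

The synthetic designs reproduce the structural features that drive the
method comparison: a known fixed threshold, beta-shaped biomarker
distributions of varying skewness, calibrated signal-to-noise, moderate to
strong covariate correlation, and a controlled non-linearity. They do not
emulate several features of real laboratory data: multiple or time-varying
detection limits, measurement error above the limit, heteroscedastic or
non-normal residuals, missingness unrelated to the limit, or many
covariates. Conclusions from passing tests therefore speak to the methods'
behaviour under these controlled conditions, not to every real data set.

## Problem sizes used by the shipped tests

The test suite and the acceptance script run desk-scale versions of the
study: populations of 100,000 rows for calibration and MSE, scenario grids
at $n = 1000$ with 200 replicates for the qualitative method orderings,
500 replicates for unbiasedness/recovery checks and 1000 replicates for
the coverage calibration, with correlations checked on samples of
$10^5$. The shipped configuration `inst/extdata/desk_grid.yaml` covers both
models, all settings, $n \in \{45, 300, 1000\}$ and five censoring
proportions at 200 replicates; the full study grid is reachable by editing
its lists.

## Known limitations

* Only one variable per dataset may be censored, from below, at a single
  fixed threshold; right- or interval-censoring and multiple limits are
  out of scope.
* The tobit fit assumes normal residuals; no robust or distribution-free
  censored-outcome estimator is provided.
* The truncated kNN rule degenerates to LLOQ-substitution whenever no
  donor lies below the threshold (see above) — in the built-in simulation
  designs this is always the case, so the kNN and LLOQ-substitution curves
  coincide there by construction.
* Population MSE depends on the completion convention for the discard
  method, which is a package choice, not an intrinsic property of
  discarding.
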