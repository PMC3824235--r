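---
title: "A longitudinal measurement error model for dietary self-reports with a surrogate biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A longitudinal measurement error model for dietary self-reports with a surrogate biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietme)
```

## The problem

Nutritional epidemiology estimates diet–disease associations almost
exclusively from error-prone measurements of intake: food frequency
questionnaires (FFQs) and food records such as 7-day diaries. Errors in
these instruments are not benign white noise — they depend on the true
intake level (scaling bias), they persist within a person across repeat
administrations, and errors of the two instrument types are correlated
with each other. Random error attenuates estimated log odds or hazard
ratios; systematic error can push them in either direction. Regression
calibration corrects an observed association by dividing by the
*regression dilution ratio* (RDR)
$\lambda_{XT} = \mathrm{cov}(X, T)/\mathrm{var}(X)$, the slope of true
intake $T$ on the measurement $X$ — so everything rests on estimating
$\lambda$ well.

For most foods and nutrients there is no unbiased ("recovery")
biomarker. What is often available is a *surrogate* (concentration)
biomarker — a biological measure correlated with intake but also driven
by absorption, metabolism and individual traits; plasma vitamin C as a
marker of fruit and vegetable intake is the canonical example. A
surrogate biomarker lets one relax the independence assumptions that
FFQ-vs-record validation designs require, at the price of *new*
untestable assumptions. `dietme` implements a model that makes those
assumptions explicit and quantifies, by sensitivity analysis, how much
the conclusions depend on them.

## The model

For individual $i$ at time point $j = 1, \dots, J$, let $T_i$ be
long-term average intake and $T_{ij} = T_i + h_{ij}$ the time-specific
intake, with $h_{ij} \sim N(0, \sigma^2_{hj})$ independent over time and
of $T_i$. Conditional on covariate blocks $Z$, with
$T_i \mid Z \sim N(\cdot, \sigma^2_T)$, the three measurements are

$$
\begin{aligned}
Q_{ij} &= \alpha_{Qj} + \beta_Q T_{ij} + \gamma_Q' Z_{Qij} + \epsilon_{Qij}
&& \text{(FFQ, log scale)}\\
R_{ij} &= \alpha_{Rj} + \beta_R T_{ij} + \epsilon_{Rij}
&& \text{(food record, log scale)}\\
M_{ij} &= \alpha_{Mj} + \beta_M T_{ij} + \gamma_M' Z_{Mij} + \epsilon_{Mij}
&& \text{(biomarker, natural scale)}
\end{aligned}
$$

with zero-mean normal errors of time-specific variances
$\sigma^2_{Qj}, \sigma^2_{Rj}, \sigma^2_{Mj}$. The error correlation
structure is the scientific heart of the model:

* repeated self-report errors are correlated
  ($\rho_{QQ}^{(jk)}$, $\rho_{RR}^{(jk)}$), capturing person-specific
  reporting tendencies;
* FFQ and record errors are correlated, more strongly at the same time
  point ($\rho_{QR}^{(jj)}$) than across time points
  ($\rho_{QR}^{(jk)}$, kept *ordered*: the error of $Q$ at $j$ with $R$
  at $k$ is a different parameter from $Q$ at $k$ with $R$ at $j$);
* self-report and biomarker errors are uncorrelated given the
  covariates — the assumption that buys identifiability and motivates
  adjusting for characteristics (sex, age, BMI, smoking) that plausibly
  affect both reporting and the biomarker;
* repeated biomarker errors have correlation $\rho_{MM}$.

Two parameters are **not identified** by any amount of data of this
design: the record scaling $\beta_R$ (one instrument must have
systematic bias of known form; setting $\beta_R = 1$ is the
conventional, optimistic choice) and $\rho_{MM}$ (surrogate biomarkers
are affected by stable intrinsic factors — genetics, metabolism — that
covariates cannot fully capture, so assuming $\rho_{MM} = 0$ is
hazardous). `dietme` holds the pair fixed in a
`sensitivity_setting()` and refits over a grid, by default
$\beta_R \in \{1, 0.75, 0.5\}$ (the range recovery-biomarker studies
report for food records) crossed with $\rho_{MM} \in \{0, 0.2, 0.4\}$.
Also fixed for identifiability: $\gamma_R \equiv 0$ (record reporting
unrelated to covariates — its value would only shift
$\gamma_T, \gamma_Q, \gamma_M$), and $\alpha_T = 0$ with no covariate
intercept for $T$ (these only relabel the other intercepts).

Degrees of freedom are checked combinatorially by `dof_check()`: at
$J = 2$ with all six measurement slots the covariance structure has 17
free parameters against 21 observed second moments; at $J = 1$ the
same-time error correlation $\rho_{QR}^{(11)}$ must be fixed (7 free
vs 6 moments otherwise), and $\sigma^2_h$ is absorbed into
$\sigma^2_T$.

## Derived quantities

With the implied conditional variance
$v_{Xj} = \beta_X^2(\sigma^2_T + \sigma^2_{hj}) + \sigma^2_{Xj}$,

$$
\lambda^{lt}_{Xj} = \frac{\beta_X \sigma^2_T}{v_{Xj}}, \qquad
\lambda^{ts}_{Xj} = \frac{\beta_X (\sigma^2_T + \sigma^2_{hj})}{v_{Xj}},
\qquad
\mathrm{corr}(X_{ij}, T_i \mid Z) = \frac{\beta_X \sqrt{\sigma^2_T}}{\sqrt{v_{Xj}}},
$$

for exposure defined as long-term ($T_i$) or time-specific ($T_{ij}$)
intake. The time-specific RDR always dominates the long-term one when
$\sigma^2_{hj} > 0$ (same denominator, larger numerator) — self-reports
track recent intake better than habitual intake. RDRs can exceed 1:
measurement error can *amplify* an association, and correcting under
wrong assumptions ($\beta_R = 1$, $\rho_{MM} = 0$ give the smallest
RDRs) can badly overcorrect. These closed forms were derived from the
model's covariance algebra and are verified in the test suite against
brute-force regressions of simulated latent truth on simulated
measurements at $n = 10^6$.

Two exact structural facts double as test oracles:

* **Scaling law.** Replacing $\beta_R \to c\,\beta_R$ maps the MLE by
  $\hat\beta_Q \to c\hat\beta_Q$, $\hat\beta_M \to c\hat\beta_M$,
  $\hat\sigma^2_T \to \hat\sigma^2_T/c^2$,
  $\hat\sigma^2_h \to \hat\sigma^2_h/c^2$, leaves error variances and
  correlations untouched, divides every RDR by $c$, and leaves every
  correlation with truth unchanged. This is a likelihood-preserving
  reparameterization, so it holds exactly at the optimum.
* **$\rho_{MM}$ invariance of $\hat\beta_Q$.** Changing $\rho_{MM}$
  reallocates biomarker covariance between true-intake variance and
  error structure, but the questionnaire scaling is pinned by
  cross-instrument moment ratios and does not move.

When the diet–disease model uses untransformed intake while the error
model lives on the log scale, `backtransform_rdr()` estimates the
original-scale RDR by Monte Carlo: simulate $(T, X)$ from the fitted
bivariate normal, exponentiate, take the least-squares slope. The
reported Monte-Carlo SE is heteroskedasticity-robust (sandwich), because
the exponentiated variables are heavy-tailed and the homoskedastic
slope SE understates the Monte-Carlo noise several-fold.

## Fitting

`fit_ml()` maximizes the multivariate-normal likelihood of the observed
subvector per individual, grouped by missingness pattern with
per-pattern sufficient statistics, so one likelihood evaluation costs
$O(\text{patterns} \times (3J)^2)$ regardless of $n$. All individuals
with at least one measurement contribute ("full cohort"); this is valid
and efficient under missing at random, and a test demonstrates the
contrast: with 40% MAR missingness in second-visit record and biomarker
driven by the first FFQ, the full-cohort fit recovers $\sigma^2_T$
within sampling error while complete-case fitting is biased by many
standard errors.

Numerical choices:

* **Parameterization.** Log for variances, Fisher-$z$ (atanh) for
  correlations, identity for scalings and intercepts. Box constraints
  cannot guarantee joint positive definiteness, so every likelihood
  evaluation attempts a Cholesky factorization and returns a $-\infty$
  sentinel on failure; the optimizer never crashes.
* **Starting values.** Moment-based: cross-instrument different-time
  covariances isolate $\beta_M \sigma^2_T$ and $\beta_Q \beta_M
  \sigma^2_T$ (they carry no error correlation), the between-biomarker
  covariance then splits $\beta_M$ from $\sigma^2_T$ given $\rho_{MM}$,
  and the remaining variances and correlations follow by substitution,
  with clipping and a neutral fallback wherever the inversion fails.
  Correlation starts are shrunk toward zero until the error-correlation
  matrix is positive definite.
* **Optimization.** BFGS with numerical gradients, then alternating
  PORT/BFGS polish rounds until the objective improves by less than
  $10^{-10}$ relative — the likelihood is flat along ratio directions
  (e.g. $\beta_M$ vs $\sigma^2_T$) and a single pass can stop short.
  Optional jittered multistarts guard against local optima, which the
  likelihood can develop at large $\rho_{MM}$.
* **Standard errors.** Delta method through the inverse observed
  information (numerical Hessian on the transformed scale, numerical
  Jacobian for RDRs/correlations), or a nonparametric bootstrap over
  individuals warm-started at the point estimate. The two agree to
  within Monte-Carlo noise in the tests; the method is an
  implementation choice, and parameters fixed by the sensitivity
  setting are reported with SE exactly 0.
* **Intercepts.** After `residualize()` (see below) means are exactly
  zero and intercepts are fixed; on raw data free time-specific
  intercepts are estimated. Under MAR the intercepts must stay free:
  observed-subsample means are selection-biased, so demeaning columns
  before fitting would corrupt the likelihood (the full likelihood
  handles the means correctly).

Covariates enter by the two-step residual procedure: each measurement
is replaced by its OLS residual on the concatenation of its own
covariate block and the true-intake block, per instrument and time
point; the covariance model is then fitted to residuals.
Covariate effects themselves come from random-intercept linear mixed
models (ML, via `lme4`): $\gamma_T$ from regressing the record on
$Z_T$ and dividing by $\beta_R$; $\gamma_Q$ and $\gamma_M$ from
regressing the constructed responses
$Q - \hat\beta_Q R/\beta_R$ and $M - \hat\beta_M R/\beta_R$ on their
blocks, with the caveat (documented in the return) that these SEs
ignore the uncertainty in $\hat\beta$. Unconditional RDRs and
correlations, when wanted, are obtained by fitting without covariate
blocks.

## The sensitivity grid

`run_grid()` fits every $(\beta_R, \rho_{MM})$ cell on the identical
preprocessed dataset. Within a $\rho_{MM}$ row, cells after the first
are warm-started from the *exactly rescaled* solution of the row's
first cell — legitimate because the rescaling preserves the likelihood,
and it makes the scaling law hold across reported cells to $\sim
10^{-9}$ instead of bare optimizer noise; a test verifies that warm-
and cold-started fits agree. Failed cells are recorded with their
diagnostic and rendered as `NC`, never silently dropped.
`summarize_grid()` lays results out with $\rho_{MM}$ as columns and
(quantity, time, exposure, $\beta_R$) as rows — `estimate (se)` strings
for reading, a long-format CSV twin for machines. Subset analyses
(e.g. supplement users vs non-users) are row filters via
`subset_me_data()` ahead of `run_grid()`; no bespoke code. The package
deliberately does not pick a "most plausible" cell: that is a
scientific judgement (external evidence on the biomarker), not an
algorithm.

## The synthetic-data generator

No public dataset carries this design, so `gen_dataset()` *is* the test
bed. It draws latent truth ($T_i$, then $h_{ij}$), a $3J$-dimensional
error vector with the full correlation structure (including
$\rho_{MM}$ and the zero self-report–biomarker blocks), covariates
(binary / continuous / dummy-coded categorical, time-constant or
time-varying) with their $\gamma$ effects, and assembles the
measurements. A master seed expands into independent substreams
(covariates, truth, errors, missingness, artifacts), so changing the
missingness mechanism leaves the latent truth bit-identical. Latent
truth is returned as an attribute for oracle tests and never leaks into
the measurement columns. Missingness is MCAR (per-slot rates) or MAR
(logistic deletion on a standardized observed driver slot); raw-scale
artifacts emulate reported zero intakes (Q/R set to 0) and spuriously
high biomarker values (multiplied by a factor, as supplement use would).

The default parameters (`fv_example_params()`) are of the magnitude
seen in large validation studies of fruit and vegetable intake:
self-reports on the log g/day scale with error variances 0.17–0.41 and
error correlations 0.1–0.65, a biomarker in concentration units
($\beta_M \approx$ 12–50 per log-unit of intake, error variances in the
hundreds), between-person intake variance 0.07–0.37 depending on the
sensitivity cell, and within-person variance an order of magnitude
smaller. What the generator does **not** emulate: real covariate
distributions and seasonal calendars, non-normality on the analysis
scale, covariate-dependent error variances, or correlated $h_{ij}$.
Passing tests therefore certify the estimator under the model's own
assumptions — not robustness to their violation.

## Preprocessing

`preprocess()` takes raw-scale data to the analysis scale: zero or
negative self-report values become missing before logging (a reported
zero over a recall period is uninformative about log-scale habitual
intake); biomarker values strictly above $Q_{0.75} + 2 \times IQR$,
computed per time point with linear-interpolation quantiles (the common
statistical-software convention; both the multiplier and the quantile
are configurable), become missing as probable supplement-use artifacts;
then the configured instruments are logged. The step is idempotent,
logs every exclusion count, and the counts are tested to equal the
before/after cell difference.

## Problem sizes and what the tests show

The test suite generates all data programmatically: moment-oracle
equivalence over 20 random parameter draws at $n = 10^6$; closed-form
RDR/correlation vs brute-force regression at $n = 10^6$; parameter
recovery and interval calibration over 20 replicates of $n = 20{,}000$
at a realistic parameter set with $(\beta_R, \rho_{MM}) = (0.75, 0.4)$;
the scaling law at $10^{-4}$ relative and the $\rho_{MM}$ invariance at
$10^{-3}$ relative on fixed data; the recovery-biomarker moment
estimator reproduced within 0.01 at $n = 2 \times 10^5$; the MAR
contrast at $n = 20{,}000$ with 40% missingness; and analytic spot
checks (standard-normal log-density, classical attenuation $\lambda =
1/2$, the lognormal back-transform closed form). Sizes were chosen so
Monte-Carlo noise sits well below the tolerances being asserted.

## Known limitations

* The two-step residual adjustment is exact only when covariate
  regressions are estimated from data missing (at most) completely at
  random; under covariate-dependent MAR the one-step likelihood with
  free intercepts is preferable.
* $h_{ij}$ independent over time and of covariates; error variances
  independent of covariates; no random biomarker slope. All are
  extensions the model structure could absorb at the cost of
  covariate-dependent RDRs.
* Single dietary exposure; multivariate (multi-nutrient) error models
  and estimating-equation fitting are out of scope.
* Mixed-model SEs for $\gamma_Q, \gamma_M$ ignore uncertainty in the
  plugged-in scalings.

```{r example, eval = FALSE}
## a complete small analysis
sens <- sensitivity_setting(beta_R = 0.75, rho_MM = 0.4)
d <- gen_dataset(simulation_spec(n = 5000, params = fv_example_params(sens),
                                 sens = sens, seed = 1))
res <- run_grid(residualize(d), sensitivity_grid())
summarize_grid(res, "rdr")
```
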