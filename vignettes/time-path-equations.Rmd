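---
title: "Modelling risk-factor time paths in type 2 diabetes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk-factor time paths in type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndrpath)
```

## The model

Each of the five cardiovascular risk factors (HbA1c in % DCCT, systolic BP
on a mmHg/10 scale, BMI in kg/m², TC:HDL, LDL in mmol/L) follows a
first-order linear dynamic equation

$$RF_{it} = \alpha\, RF_{i,t-1} + \beta' x_{it} + \mu_i + \nu_{it},$$

with years $t = 1, 2, \dots$ counted from the year of diabetes diagnosis
($t = 0$ carries the baseline measurement).  The covariate vector contains
$\ln t$ (duration enters logged because its distribution is skewed), a
first-year indicator (HbA1c only, capturing the sharp post-diagnosis drop
under newly initiated treatment), age at diagnosis, female sex, current
smoking, current BMI and — in the LDL equation — BMI squared.  $\mu_i$ is a
permanent patient effect, $\nu_{it}$ an i.i.d. shock.

Two consequences of $0 < \alpha < 1$ organise everything the package does:

* **Convergence.** Conditional on covariates, paths approach the fixed
  point $(\,c + \beta'x\,)/(1-\alpha)$ geometrically at rate $\alpha$
  (`steady_state()`); differences between patients shrink by the factor
  $\alpha$ per year.
* **Short- vs long-term effects.** A sustained one-unit covariate change
  moves the risk factor by $\beta$ in the same year and by
  $\beta/(1-\alpha)$ in the limit (`long_term_effect()`).

## The trajectory engine

`simulate_path()` iterates the five equations jointly.  Design choices
that were genuinely open, and how they were resolved:

* **Contemporaneous BMI coupling.**  BMI is updated first each year and
  the *same-year predicted* BMI (and its square) enters the other four
  equations.  The alternative — lagged BMI — is structurally defensible,
  but the contemporaneous form is what reproduces the published
  illustrative predictions to their printed precision, and it matches the
  equations' estimation layout, where current-year BMI is a regressor.
* **Significance filtering.**  Prediction uses covariates significant at
  the 10% level by default, the convention under which the equations were
  validated; `level = "none"` keeps every estimated coefficient for
  sensitivity analysis.  The constant and lag coefficient are never
  filtered.  Filtering is idempotent, and filtered-out values are removed
  (not zeroed in place) so that a filtered set serialises cleanly.
* **Smoking.**  Baseline smoking status is held fixed along the path —
  follow-up data show little within-patient change (about 70% of baseline
  smokers and 95% of baseline nonsmokers keep their status) and a model of
  smoking dynamics is deliberately out of scope.  A user-supplied
  `smoking_path` overrides the freeze, e.g. to study a quit scenario.
* **Units.**  All public interfaces use clinical units; the /10 SBP scale
  and any Mono-S→DCCT conversion are handled internally at the boundary.

### Printed-coefficient rounding

The shipped coefficient set stores the published values, which are rounded
to three decimals.  Iterating rounded coefficients accumulates drift
against predictions produced from unrounded estimates: for SBP (lag 0.466,
values ≈ 13.8 on the model scale) the drift reaches ≈ 0.07 mmHg by year 5,
and for BMI (lag 0.811, values ≈ 29) ≈ 0.01 kg/m² by year 5.  The golden
tests therefore allow ±0.01 on HbA1c/TC:HDL/LDL cells, ±0.015 on BMI cells
and ±0.1 mmHg on SBP cells; these bounds follow from a worst-case
rounding propagation of ±0.0005 in the lag coefficient alone and are far
tighter than what rounding of the remaining coefficients could justify.

## System GMM estimation

With a lagged dependent variable and patient effects, pooled OLS is
inconsistent: $RF_{i,t-1}$ is correlated with $\mu_i$, biasing
$\hat\alpha$ upward (the package's `pooled_ols()` demonstrates this on any
synthetic cohort).  `dpm_gmm()` implements the Blundell–Bond system
estimator from first principles in base R:

* the **differenced equation** removes $\mu_i$ and is instrumented by
  lagged levels — lags ≥ 2 of the dependent variable, lags ≥ 2 of
  endogenous regressors (e.g. smoking in the HbA1c equation, which may
  respond to past HbA1c), lags ≥ 1 of predetermined regressors (current
  BMI), and the first differences of strictly exogenous regressors;
* the **levels equation** is instrumented by lagged differences
  ($\Delta RF_{i,t-1}$, $\Delta x_{it}$ or $\Delta x_{i,t-1}$ by
  classification) and the exogenous regressors themselves.  Time-invariant
  covariates (age at diagnosis, sex) are identified through this part.

Moment conditions are assembled from whatever valid (patient, period, lag)
combinations exist, so unbalanced panels and gaps need no special
handling: a gap breaks differencing across it but leaves deeper-lag
instruments intact.

Numerical and procedural choices:

* **Weighting.**  One-step weighting uses the block matrix with the
  standard tridiagonal pattern (2 on the diagonal, −1 for adjacent
  periods) for differenced rows, the identity for levels rows and zero
  cross blocks.  Two-step weighting inverts the clustered moment
  covariance of the one-step residuals; the inverse is a Moore–Penrose
  pseudo-inverse (SVD, relative tolerance 1e-10) because that matrix is
  routinely rank-deficient when instruments are numerous.  Two-step is the
  default, with the Windmeijer finite-sample correction to the standard
  errors (without it, two-step standard errors are well known to be
  severely downward biased).
* **Instrument proliferation.**  `collapse = TRUE` (default) keeps one
  column per (variable, lag) instead of one per (variable, lag, period);
  `max_lag` caps lag depth.  Defaults favour a modest instrument count,
  which keeps the Hansen test informative.
* **Diagnostics.**  `hansen_test()` is the two-step J statistic on
  instruments-minus-parameters degrees of freedom (undefined and
  explicitly signalled for just-identified models).  `ar_test()` is the
  Arellano–Bond statistic on first-differenced residuals with the full
  three-term variance (including the parameter-estimation terms); AR(1)
  rejection is expected by construction, AR(2) rejection flags
  misspecification.  Degenerate cases (constant residuals, too few
  periods for order 2) raise explicit errors rather than returning
  numbers.
* **Failure modes.**  Under-identification (more parameters than surviving
  instrument columns) and exactly collinear designs produce targeted error
  messages; identically zero instrument columns (e.g. differences of
  time-invariant regressors) are dropped silently.

In a Monte Carlo under a correctly specified design (one equation,
$\alpha = 0.5$, one predetermined covariate, n = 500 patients, 7 follow-up
years, 200 replicates — sized so that the simulation error of a 5%
rejection rate is ≈ 1.5 points), the estimator is mean-unbiased to three
decimals, 95% confidence intervals cover at ≈ 96%, the Hansen test rejects
≈ 4–5% of the time at the 5% level, AR(1) rejects always and AR(2) at
≈ 5%.  The test suite re-runs this study, plus power checks in which MA(1)
shocks (invalid lag-2 instruments) drive Hansen p-values to zero and
autocorrelated shocks trip AR(2).

## The synthetic cohort generator

`generate_cohort()` emulates the register panels the equations come from:
diagnoses staggered over 2001–2004, administrative censoring at the end of
2008 (so 4–7 follow-up years), per-sex baseline means/SDs and smoking
prevalences from the published cohort table, annual dropout (default 5%),
per-measurement missingness (default 10%), and forward simulation of the
five equations with BMI simulated first each year.  All randomness flows
from one seed, and the generator's paths collapse exactly onto
`simulate_path()` when the noise, dropout and missingness are switched off.

Two conventions deserve emphasis because the register values they replace
are unpublished:

* **Variance split.**  The within/between split of the cross-sectional
  variance $s^2$ (SDs from the published baseline table) is not reported.
  The default assigns half to the permanent effect,
  $\sigma_\mu = (1-\alpha)s/\sqrt2$, and half to the transient part,
  $\sigma_\nu = s\sqrt{(1-\alpha^2)/2}$.  Both are exposed as parameters.
* **Mean-stationary baselines.**  Baselines are drawn as
  sex mean $+\ \mu_i/(1-\alpha) + d_i$, i.e. they include the patient's
  steady-state share of the permanent effect.  With the variance split
  above this makes the simulated cross-section *variance-stationary* (the
  SD equals $s$ in every follow-up year, as register data roughly show)
  and — more importantly — *mean-stationary*, which is precisely the
  condition under which the levels-equation instruments of system GMM are
  valid.  The marginal baseline distribution is still normal with the
  published mean and SD.  Drawing baselines independently of $\mu_i$ would
  silently violate the estimator's own assumptions and is therefore not
  offered as a default.

Features of real register data the generator does **not** emulate — so
passing tests say nothing about them: correlated baseline risk factors
(defaults are independent per sex), informative dropout or missingness
(both are completely at random here), treatment effects and treatment-risk
feedback (a crude age-dependent treatment class exists only to exercise
the inclusion filter), assay or measurement error, and the later start of
lipid recording.  Smoking persistence (defaults 0.70/0.95) is interpreted
as the probability that baseline status is unchanged over the whole
follow-up — the published figures are end-of-follow-up proportions, not
annual hazards — with non-persistent patients switching once at a
uniformly drawn year.

`apply_inclusion_criteria()` reproduces the cohort definition: diagnosis
in 2001–2004, age 25–70 at diagnosis, non-missing baseline smoking and
BMI, the type 2 treatment definition (diet/oral agents at any age;
insulin regimens only with onset age ≥ 40), and at least three
measurements — at diagnosis plus two in follow-up — of the risk factor
being modelled.  `yearly_average()` implements the one-record-per-year
convention (arithmetic mean of repeated within-year measurements).

## Temporal validation

`validate_panel()` rolls per-patient predictions forward from
diagnosis-year baselines (10% filter; predicted, not observed, BMI feeds
the other equations, because a real application has no observed follow-up
BMI either), aligns them with observed patient-years up to 3 years after
diagnosis (the horizon is configurable), and reports per risk factor and
subgroup (sex × baseline smoking, plus the whole sample) the slope,
intercept and one-sided p-value of the observed-on-predicted regression —
the alternative hypothesis is positive association — and the RMSE of every
candidate coefficient set.  Comparator sets (e.g. the UKPDS outcome-model
equations, which the package does not ship) are supplied by the user as
coefficient files.  The observed-on-predicted regression is computed in
closed form so that the noise-free self-consistency case (slope exactly 1,
zero residual variance, infinite t) is handled without warnings.

The parameter-recovery study in the test suite uses cohorts of n = 2000
patients diagnosed in 2001 (7 follow-up years) over 50 replicates, with
the shipped coefficients as truth and the default error SDs; the RMSE
model-comparison study uses 100 held-out cohorts of n = 150 with the lag
coefficients of the comparator perturbed by +0.08.  These sizes give
per-equation mean absolute errors on $\hat\alpha$ well under 0.02 while
keeping the whole suite comfortably fast on a single CPU.

## Known limitations

* The shipped coefficients are rounded to three decimals, so published
  illustrative cells are reproduced to ≈ 0.01 (≈ 0.1 mmHg for SBP), not
  exactly; see the rounding analysis above.
* The estimator offers the system (Blundell–Bond) family only; the
  difference-only (Arellano–Bond 1991) estimator exists merely as the
  degenerate configuration in which levels instruments contribute nothing.
* Only contemporaneous covariate effects are modelled; lagged covariate
  effects (e.g. last year's smoking on this year's BMI) are out of scope,
  as is any stochastic trajectory simulation with drawn shocks — the
  engine is deterministic by design, and event/complication equations are
  a different layer of a health-economic model.
* Predictions assume the 10%-filter convention transfers to the user's
  population; refitting with `dpm_gmm()` on local data is the intended
  remedy when it does not.
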