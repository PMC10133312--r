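---
title: "Statistical cure and years of life lost after ablation of HCC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical cure and years of life lost after ablation of HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curablate)
library(survival)
```

## The question the package answers

Radiofrequency and microwave ablation are offered to patients with early
hepatocellular carcinoma (HCC) as "potentially curative" treatments, but the
word *curative* is rarely quantified. The statistical-cure framework makes it
concrete: a treated cohort is (statistically) cured when its survival — here
*disease-free* survival, because a patient alive with recurrent tumour is not
cured — becomes indistinguishable from that of a matched general population.
The proportion of patients reaching that state is the cure fraction; the time
at which a still disease-free patient can be declared cured with a chosen
certainty is the time-to-cure; and the difference between the life expectancy
of the matched reference individual and the mean survival of the treated
patient is the years of life lost (YLL, loss in expectation of life).

curablate implements that full pipeline: national-life-table background
mortality, a flexible parametric non-mixture cure model on the
relative-survival scale, cure-fraction / time-to-cure / YLL prediction, the
additive re-fit that turns per-patient YLL into a bedside formula, a
published-coefficient calculator, and a synthetic-cohort generator so the
whole chain can be validated without access to patient data.

## Relative survival and the non-mixture cure model

Let `S*(t)` and `h*(t)` be the expected survival and hazard of a reference
individual matched on sex, age and calendar year, taken from a national life
table. The observed all-cause disease-free survival factorises as

    S(t | x) = S*(t) · R(t | x),

where `R` is the relative (net) survival and its negative log,
`Lambda(t | x)`, is the cumulative *excess* hazard attributable to the
disease. The model is a spline-based (Royston–Parmar-type) parametrisation of
the log cumulative excess hazard,

    log Lambda(t | x) = gamma_0 + sum_j gamma_j v_j(log t) + x' beta,

with a *cure-constrained* basis: every `v_j` is a cubic spline of log time,
linear below the first knot, and **exactly zero at and beyond the last
knot**. The constraint is the statistical content of cure: beyond the last
knot the cumulative excess hazard cannot grow, the relative survival
flattens, and the plateau is

    pi(x) = exp(-exp(gamma_0 + x' beta)),

which is precisely the published prediction equation of the bedside
calculator (`exp(-exp(constant + x1 b1 + ... + xn bn))`). This identity is
why the non-mixture formulation was adopted: the printed coefficient set *is*
the plateau of such a model. The mixture variant (`R = pi + (1-pi) S_u`) is
deliberately out of scope. Covariates act proportionally on the cumulative
excess hazard (one coefficient per covariate, no time-varying effects),
matching the structure of the published multivariable table.

### Basis construction

With knots `k_1 < ... < k_K` (placed at equally spaced centiles of the log
*uncensored* event times; `df = 4`, i.e. 5 knots, by default), each basis
function is a truncated-power cubic evaluated at `u = min(x, k_K)` with its
right-boundary slope removed and its plateau value subtracted, so that
`v_j(k_K) = 0` and `v_j'(k_K) = 0` exactly. The functions are continuous with
continuous first derivative; each column is rescaled by its standard
deviation over the data to condition the optimisation (the rescaling cannot
move the plateau, which is pinned at zero). Because the basis vanishes at the
plateau, `gamma_0 + x' beta` *is* `log Lambda(infinity)` — no extrapolation
or basis evaluation is needed to read off the cure fraction.

### Likelihood and optimisation

For subject `i` with DFS time `t_i`, event indicator `d_i` and background
hazard `h*_i(t_i)` evaluated at the exact attained age and calendar year, the
log likelihood (dropping the additive `log S*` terms, which do not involve
parameters) is

    l = sum_i d_i log( h*_i(t_i) + lambda_i(t_i) ) - Lambda_i(t_i),

with `lambda = dLambda/dt`. The excess hazard of a spline model is not
automatically non-negative; where a parameter excursion drives the total
hazard at an event below `1e-8`, the log is continued linearly
(`log eps + x/eps - 1`), which keeps the objective finite and pushes the
optimiser back into the valid region. At the last knot the basis slope is
exactly zero, so an event at the largest event time has zero *excess* density
by construction; its contribution is carried by the background hazard (and by
the linearised guard in the degenerate zero-background case, where it is a
constant and cannot distort the fit).

Optimisation is BFGS with analytic gradients, multi-started from an
intercept grid (`-1, -0.5, 0, 0.5`) around a crude start obtained by
regressing the log cumulative hazard of the Kaplan–Meier curve on the basis;
the best converged start wins, relative function tolerance `1e-8`. The
covariance matrix is the inverse of the observed information (numerically
differentiated gradient); a singular information matrix falls back to a
pseudo-inverse with a warning.

### Covariate selection

`select_cure_model()` mirrors the conventional epidemiological two-stage
workflow: univariable screening keeps terms with joint Wald `p < 0.10`, and
backward elimination then removes the worst term until all retained terms
have `p < 0.05`. The screening threshold is the published one; the published
analysis does not state its final retention criterion, so 0.05 (the
conventional choice) is the documented, configurable default. The returned
fit carries the full selection trail (every screen, removal, and the final
p-values).

## Life tables

Life tables store *rates* (events per person-year), not annual death
probabilities, because piecewise-exponential integration is then exact;
`prob_to_rate()` converts published `q_x` via `mu = -log(1 - q)`. Attained
age and attained calendar year advance together in real time from the origin
(the Lexis diagonal), so a subject aged 60.4 in mid-2010 is looked up at age
61 from `t = 0.6` onward. Beyond the tabulated age or year range the nearest
stratum is used — WHO tables end in an open age group and clamping is the
least-surprising closure. Fractional ages at the origin are kept; integration
cells break at every integer-age and integer-year crossing, and
`expected_survival()` / `expected_residual_life()` accumulate the
piecewise-exponential cells analytically. Cohort-level expected survival is
obtained by averaging individual trajectories (an Ederer II-style
convention; the published analysis does not state which convention its
software used).

## Time-to-cure and years of life lost

The conditional probability that a patient still disease-free at `t` is
cured is `pi / R(t) = exp(Lambda(t) - Lambda(infinity))`, which increases to
1 at the plateau. `time_to_cure()` returns the earliest `t` at which it
reaches the requested certainty (90% in typical use), solved by bisection to
`1e-6` years; a certainty of exactly 1 returns the plateau onset `exp(k_K)`.

`model_mean_survival()` integrates `S*(t) R(t)`. Up to the spline plateau
the integral uses a composite trapezoid with step 0.05 years and exact
`S*`; beyond the plateau `R` equals `pi`, so the tail is
`pi * int S* dt`, accumulated analytically over the life-table cells — the
extrapolation of the relative survival beyond follow-up is the plateau
value, a property of the cure model, not an added assumption. The default
horizon is `min(120 - age, 100)` years; on realistic tables, doubling the
horizon beyond age 110 moves the result by less than 0.01 years because the
integrand is annihilated by background mortality first (this is asserted in
the test suite). `years_of_life_lost()` subtracts the model mean survival
from the reference mean residual life at the same horizon, so
`e_ref = e_model + yll` holds by construction.

The per-patient YLL predictions are then re-fitted with an identity-link
Gaussian linear model (`refit_yll_glm()`, ordinary least squares on age and
the model covariates), reproducing the published additive approximation and
reporting `R^2 = 1 - SSE/SST`.

## The bedside calculator

`calculator_coefficients()` bundles the two published multivariable
coefficient sets — cure probability (log(-log) scale) and approximate YLL
(identity scale) — exactly as printed, with reference categories
contributing zero. `cure_probability()` and `yll_approximation()` evaluate
them for a `patient_profile()`; hepatitis B, which enters only the YLL
equation, is imputed at the cohort mean 0.495 when unspecified. Negative
approximate losses (possible only above roughly age 83 with favourable
profiles) are clipped at zero with a warning, since a negative loss of life
is not meaningful.

Reproducing the published example grid requires representative continuous
values that the source table reports only as categories. The package uses
tumour size 1.9 cm for "<2 cm" rows, 2.5 cm for "2–3 cm" rows, ages
55/65/75 for the three age columns, and treatment from 2014 onward; these
are reverse-engineered — they regenerate the printed grid to rounding
precision under the printed coefficients — and are documented as such
rather than as authorial statements. `classify_percentiles()` bands values
at the published cohort quartiles (cure 11.9%/26.0%; YLL 11.5/22.7 years),
with boundaries assigned to the upper band (inclusive lower edge).

## The synthetic cohort generator

`simulate_cohort()` is the package's test bed. Its defaults emulate the
study conditions: the published covariate marginals (76.2% male, era shares
10.6/33.3/56.1%, HBV 49.5%, HCV 22.9%, ALBI grades 37.7/55.2/7.1%,
single/2–3/4+ nodules 74.9/21.6/3.5%, size log-normal with median 2.5 cm
and IQR 1.9–3.4, age roughly normal with median 62 and IQR 54–70), the
published multivariable cure coefficients as the generating truth, a
Weibull excess-event time for uncured patients (shape 1.2, median 1.3
years — a loose calibration to the cohort's median DFS, documented as
such), Gompertz background mortality (`a = 5e-5`, `b = 0.095`, male rates
scaled by 1.3 and female by 0.8, giving a mid-60s hazard of roughly 2% per
year as in general-population tables), and administrative censoring uniform
on 0–15 years, reflecting recruitment spread over a decade and a half of
calendar time. Each patient carries a truth channel (cure status, the three
latent times, the event source), so observed data are always
reconstructible and estimation error is measurable.

Three honest caveats. First, covariates are drawn independently — the source
reports marginals only — so real-world dependence between age, aetiology and
liver function is not emulated, and subgroup-level agreement with the
published stratified estimates is out of reach by design. Second, the
generator is a *mixture*: cure status is drawn per patient and only the
uncured can have excess events. The fitted model is the *non-mixture*
proportional-excess-hazard spline. The cure fractions of the two coincide
(`pi(x) = exp(-exp(eta))` in both), but the time shapes differ across
covariate profiles, so fitted covariate coefficients are attenuated relative
to the generating ones even as the cohort-mean cure fraction is recovered
nearly unbiasedly — `recovery_experiment()` reports both, and its
per-coefficient table makes the attenuation visible. Passing recovery
therefore demonstrates that the plateau (the scientifically reported
quantity) is well estimated under realistic misspecification, not that every
coefficient is. Third, the generator knows nothing of centre effects,
technique differences, or recurrence-then-death multi-state pathways.

## Numerical choices, in one place

- Years are days/365.25 where dates are converted.
- Kaplan–Meier confidence intervals are Greenwood on the log(-log) scale,
  clipped to [0, 1]; the median uses the step convention (first time the
  estimate is at or below 0.5), with no interpolation.
- The cure-plausibility check compares the Nelson–Aalen increment rate over
  the last quarter of follow-up with the earlier rate; "plausible" means the
  tail rate is below 0.1 of the early rate, and fewer than 3 subjects still
  at risk in the tail makes the check inconclusive. The published criterion
  is visual; these thresholds are documented heuristics, configurable.
- Bisection tolerances: `1e-6` years (time-to-cure, simulation inversion).
- YLL integration step 0.05 years before the plateau; analytic afterwards.
- DFS times must be strictly positive; same-day events should be shifted by
  the caller (the source is silent on whether they occurred).
- Ties in event times need no special handling (continuous-time likelihood).
- Delayed entry is not modelled: the time origin is ablation for everyone.

## Problem sizes used for validation

The test suite fits cohorts of 500–3000 patients and runs the recovery
experiment at 20 replicates of n = 2000 — the scale at which the
cohort-mean cure fraction is estimated to about ±0.015 (RMSE) and
delta-method intervals attain near-nominal coverage. The acceptance script
simulates one cohort of n = 1571 (the published cohort size) for the
end-to-end pipeline and the same 20 × 2000 recovery design.

## Known limitations

The reference population is the general population, as in the source
analysis; a chronic-liver-disease reference would be more appropriate but no
such life tables exist, so cure probabilities are, if anything, slightly
conservative. Proportional excess hazards and the absence of time-varying
effects are modelling choices inherited from the published analysis, not
tested against alternatives. The plateau is constrained to begin at the last
event time; with shorter follow-up than the true cure point this inflates
the estimated excess hazard near the boundary. Confidence intervals are
Wald-type throughout.
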