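# curablate

Statistical cure and years of life lost after ablation of hepatocellular
carcinoma (HCC).

Ablation (radiofrequency or microwave) is one of the "potentially curative"
treatments for early HCC, but *curative* is rarely quantified. This package
implements the statistical-cure analysis that makes it quantitative, for
biostatisticians and hepatology researchers working with ablation cohorts:

- **Relative-survival cure model.** A flexible parametric (spline-based)
  *non-mixture* cure model for disease-free survival (DFS), fitted relative
  to the background mortality of a matched general population taken from
  national life tables. The log cumulative excess hazard is

  ```
  log Λ(t | x) = γ₀ + Σⱼ γⱼ vⱼ(log t) + x′β,
  ```

  where the cure-constrained spline basis `vⱼ` is exactly zero at and beyond
  its last knot, so the relative survival `R(t|x) = exp(−Λ(t|x))` plateaus at
  the **cure fraction**

  ```
  π(x) = exp(−exp(γ₀ + x′β)).
  ```

- **Time-to-cure**: the earliest time at which the conditional probability
  of being cured given still disease-free, `π / R(t)`, reaches a chosen
  certainty (typically 90%).
- **Years of life lost (YLL)**: life-table mean residual life of the matched
  reference individual minus the model-based mean survival
  `∫ S*(t) R(t) dt`, plus the identity-link GLM re-fit that turns
  per-patient YLL into an additive bedside formula.
- **Bedside calculator**: the published multivariable coefficient sets for
  cure probability and approximate YLL, with percentile banding.
- **Cohort utilities**: DFS derivation (recurrence/death are events;
  resection and transplantation censor), ALBI liver-function grading,
  Kaplan–Meier with Greenwood log(−log) intervals, reverse Kaplan–Meier
  median follow-up, and a cure-plausibility plateau check.
- **Synthetic cohorts**: a seeded generator reproducing the study cohort's
  covariate marginals with a known truth channel, plus a parameter-recovery
  experiment harness.

## Worked example

```r
library(curablate)
library(survival)

## Bedside calculator: woman aged 55, treated after 2014, HCV-negative,
## ALBI grade 1, single 1.9 cm tumour
p <- patient_profile(sex = "female", age_years = 55, year2014 = TRUE,
                     hcv = 0, albi_grade = 1, size_cm = 1.9,
                     nodules = "single")
cure_probability(p)   # 0.399  -> "high" band (above the 26% cohort quartile)
yll_approximation(p)  # 19.6 years of life lost, "mid" band

## Full pipeline on a synthetic cohort with known truth
sc  <- simulate_cohort(sim_config(n = 1571, seed = 1))
fit <- cure_model(
  Surv(t_dfs_years, d_dfs) ~ male + year2014 + hcv + albi2 + albi3 +
    size_cm + nodules_2_3 + nodules_4plus,
  data = sc$data, lifetable = sc$lifetable,
  bg = c(age = "age_years", sex = "sex", year = "year_ablation"))
fit
mean(cure_fraction(fit, sc$data)$pi)          # cohort-mean cure fraction
median(time_to_cure(fit, sc$data, 0.9))       # years to 90% cure certainty
years_of_life_lost(fit, sc$data[1:5, ])       # per-patient YLL
```

which prints (abridged):

```
Cure probability: 39.9% (band: high)
Approximate years of life lost: 19.6 (band: mid)

Flexible parametric non-mixture cure model (relative survival)
n = 1571  events = 1208  spline df = 4
Knots (log years): -5.3571 -0.5646  0.1994  0.8129  2.6051
Log-likelihood: -2254.95
...
Cure fraction at reference covariates: 42.1% (95% CI 33.9-50.2)

Cohort-mean cure fraction: 18.7% (true value in this simulation: 19.1%)
Median time to 90% cure certainty: 7.1 years
  e_ref e_model   yll
1 17.77    5.24 12.53
2 19.03    2.71 16.32
3  5.44    1.47  3.98
```

The reference-profile cure fraction (42.1%) is the plateau for a patient
with every covariate at its reference level; the cohort mean (18.7%) is the
clinically quoted overall figure, and in this simulation the generating
truth (19.1%) sits inside its confidence interval. Per-patient rows show the
conservation `yll = e_ref − e_model`: e.g. patient 1's matched reference
individual would live 17.8 more years on average, the fitted model gives the
patient 5.2, a loss of 12.5 years.

A thin command-line front-end wraps the same functions
(`inst/cli/curablate.R`; subcommands `simulate`, `fit`, `calc`, `km`,
`yll`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","curablate.R",package="curablate"))')" \
  calc --sex f --age 55 --year 2016 --hcv 0 --albi 1 --size 1.9 --nodules single
# {"cure_probability":0.3988,...,"yll":19.5952,"yll_band":"mid"}
```

## Documentation

The methods vignette (`vignettes/cure-modelling.Rmd`) describes the model
and its assumptions, the cure-constrained basis, the likelihood and its
numerical guards, life-table conventions, the YLL integration scheme, what
the synthetic generator does and does not emulate, and known limitations.
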