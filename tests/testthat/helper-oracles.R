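# Fixtures and independent oracles used across the suite.

library(survival)

# constant-rate life table (exponential background)
const_lifetable <- function(mu, ages = 0:110, years = 2000:2020,
                            sexes = c("male", "female")) {
  lifetable(expand.grid(sex = sexes, age = ages, year = years, rate = mu))
}

# two-step toy: rate lo below age_cut, hi at and above
step_lifetable <- function(lo, hi, age_cut, ages = 0:110, years = 2000:2020) {
  g <- expand.grid(sex = c("male", "female"), age = ages, year = years)
  g$rate <- ifelse(g$age < age_cut, lo, hi)
  lifetable(g)
}

# brute-force product-limit estimator, one step per distinct time
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    dd <- sum(time == ut[i] & event == 1)
    s <- s * (1 - dd / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# fine-grid quadrature of expected survival over a hazard-lookup table
oracle_residual_life <- function(lt, age, sex, year, horizon, n = 200000) {
  tt <- seq(0, horizon, length.out = n + 1)
  h <- expected_hazard(lt, age, sex, year, (tt[-1] + tt[-length(tt)]) / 2)
  H <- c(0, cumsum(h * diff(tt)))
  S <- exp(-H)
  sum(diff(tt) * (S[-1] + S[-length(S)]) / 2)
}

# mixture-cure cohort with no background mortality and Weibull/exponential
# excess times; returns a data frame ready for cure_model()
sim_mixture_nobg <- function(n, pi, shape = 1, scale = 1, window = 15,
                             seed = 1) {
  set.seed(seed)
  cured <- runif(n) < pi
  tex <- ifelse(cured, Inf, rweibull(n, shape, scale))
  tc <- runif(n, 0, window)
  data.frame(
    t = pmax(pmin(tex, tc), 1e-9), d = as.integer(tex <= tc),
    age_years = runif(n, 40, 80), sex = sample(c("male", "female"), n, TRUE),
    year_ablation = sample(2004:2018, n, TRUE)
  )
}

zero_lifetable <- function() const_lifetable(0)
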