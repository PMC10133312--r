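test_that("disease-free survival takes the earliest event and censors surgery", {
  # recurrence before death: event at the recurrence time
  r <- derive_dfs(ablation_date = 0, recurrence_date = 1.3, death_date = 2.0,
                  last_followup_date = 2.0)
  expect_equal(r$t_years, 1.3)
  expect_equal(r$event, 1L)

  # transplant first: censored at transplant
  r <- derive_dfs(ablation_date = 0, resection_transplant_date = 0.8,
                  last_followup_date = 4)
  expect_equal(r$t_years, 0.8)
  expect_equal(r$event, 0L)

  # alive and disease-free: administrative censoring
  r <- derive_dfs(ablation_date = 0, last_followup_date = 4.7)
  expect_equal(r$t_years, 4.7)
  expect_equal(r$event, 0L)

  # dates convert at 365.25 days per year
  r <- derive_dfs(ablation_date = as.Date("2010-01-01"),
                  death_date = as.Date("2012-01-01"),
                  last_followup_date = as.Date("2012-01-01"))
  expect_equal(r$t_years, 730 / 365.25)
  expect_equal(r$event, 1L)

  expect_error(derive_dfs(ablation_date = 0, recurrence_date = -1,
                          last_followup_date = 2), "before ablation")
  expect_error(derive_dfs(ablation_date = 0, death_date = 3,
                          last_followup_date = 2), "last follow-up")
})

test_that("ALBI score and grade follow the published cut-offs", {
  # cohort medians: albumin 40 g/L, bilirubin 16 umol/L
  a <- albi(40, 16)
  expect_equal(a$score, -0.085 * 40 + 0.66 * log10(16))
  expect_equal(a$score, -2.6053, tolerance = 1e-4)
  expect_equal(a$grade, 1L)

  b <- albi(28, 50)
  expect_equal(b$score, -1.2587, tolerance = 1e-4)
  expect_equal(b$grade, 3L)

  # the cut-off belongs to the lower grade
  expect_equal(albi(38.36, 10)$grade, 1L)   # score -2.6006, just at/below -2.60
  expect_equal(albi(24.13, 10)$grade, 2L)   # score -1.3911, just at/below -1.39
  expect_equal(albi(30, 20)$grade, 2L)
  expect_error(albi(0, 10), "positive")
})

test_that("Kaplan-Meier matches hand computation and the brute-force oracle", {
  # S(1) = 2/3; the censoring at 2 leaves one subject at risk at t = 3,
  # whose event drops the product-limit estimate to 0
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$curve$surv[km$curve$time == 1], 2 / 3)
  expect_equal(km$curve$surv[km$curve$time == 3], 0)
  # without the censoring, one event among three at each step
  km_b <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_b$curve$surv, c(2, 1, 0) / 3)

  # no events: flat at 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$curve$surv == 1))
  expect_true(is.na(km0$median))

  # without censoring the estimate is the empirical survival function
  set.seed(10)
  tt <- rexp(40)
  km1 <- kaplan_meier(tt, rep(1, 40))
  expect_equal(km1$curve$surv, 1 - ecdf(tt)(km1$curve$time))

  # oracle equivalence over 100 random tiny datasets
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    tt <- round(rexp(n, 0.5), 2) + 0.01
    dd <- rbinom(n, 1, 0.7)
    km <- kaplan_meier(tt, dd)
    or <- oracle_km(tt, dd)
    expect_equal(km$curve$surv, or$surv[match(km$curve$time, or$time)])
  }

  # Greenwood log(-log) intervals bracket the estimate inside [0, 1]
  set.seed(12)
  km2 <- kaplan_meier(rexp(200), rbinom(200, 1, 0.6))
  with(km2$curve[km2$curve$surv > 0 & km2$curve$surv < 1, ], {
    expect_true(all(lower <= surv & surv <= upper))
    expect_true(all(lower >= 0 & upper <= 1))
  })

  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(0, 1), c(1, 1)), "positive")
})

test_that("reverse Kaplan-Meier estimates median follow-up", {
  expect_equal(reverse_km_median_followup(rep(5, 8), rep(0, 8)), 5)

  # hand computation on a toy set: censorings are the events
  tt <- c(1, 2, 3, 4, 5, 6)
  dd <- c(1, 0, 1, 0, 1, 0)
  or <- oracle_km(tt, 1 - dd)
  expect_equal(reverse_km_median_followup(tt, dd), min(or$time[or$surv <= 0.5]))

  # complementing twice returns the ordinary KM median
  set.seed(13)
  tt <- rexp(100); dd <- rbinom(100, 1, 0.5)
  expect_equal(kaplan_meier(tt, 1 - (1 - dd))$median, kaplan_meier(tt, dd)$median)
})

test_that("the plateau check separates cured from exponential cohorts", {
  set.seed(14)
  n <- 500
  # cure mixture: 30% cured, uncured fail early; long clean tail
  cured <- runif(n) < 0.3
  tex <- ifelse(cured, Inf, rweibull(n, 1.2, 1.8))
  tc <- runif(n, 0, 15)
  t1 <- pmax(pmin(tex, tc), 1e-6); d1 <- as.integer(tex <= tc)
  pc1 <- plateau_check(t1, d1)
  expect_identical(pc1$status, "plausible")
  expect_lt(pc1$rate_ratio, 0.1)

  # exponential, no cure: the hazard never flattens
  tex <- rexp(n, 0.4)
  t2 <- pmax(pmin(tex, tc), 1e-6); d2 <- as.integer(tex <= tc)
  pc2 <- plateau_check(t2, d2)
  expect_identical(pc2$status, "not_plausible")
  expect_gt(pc2$rate_ratio, 0.1)

  # almost nobody left at risk in the tail window: inconclusive
  t3 <- c(seq(0.1, 1.8, length.out = 60), 2.6)
  d3 <- c(rep(1, 60), 0)
  expect_identical(plateau_check(t3, d3)$status, "inconclusive")

  expect_error(plateau_check(c(1, 1, 2, 2), c(1, 1, 1, 1)), "distinct event")
})
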