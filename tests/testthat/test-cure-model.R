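# manual relative-survival log likelihood for arbitrary parameters,
# built only from exported pieces (independent of the fitter's internals)
manual_loglik <- function(knots, gamma, beta, X, t, d, lt, age, sex, year) {
  b <- cure_basis(knots)
  V <- cure_basis_matrix(b, log(t))
  Vp <- cure_basis_deriv(b, log(t))
  eta <- gamma[1] + drop(V %*% gamma[-1])
  if (length(beta)) eta <- eta + drop(X %*% beta)
  Lam <- exp(eta)
  lam <- Lam * drop(Vp %*% gamma[-1]) / t
  hstar <- expected_hazard(lt, age, sex, year, t)
  sum(d * log(hstar + lam)) - sum(Lam)
}

toy_model <- function(beta = c(size_cm = 0.191), gamma0 = -0.9,
                      lifetable = NULL) {
  new_cure_model(knots = log(c(0.05, 0.5, 1.5, 4, 12)),
                 gamma = c(gamma0, -0.15, -0.05, -0.02, -0.01),
                 beta = beta, lifetable = lifetable)
}

test_that("the plateau of the cumulative excess hazard encodes the cure fraction", {
  m <- new_cure_model(knots = log(c(0.1, 1, 8)), gamma = c(0, -0.2, -0.1))
  # log Lambda(inf) = gamma0 = 0 at reference: Lambda plateaus at 1
  expect_equal(as.numeric(excess_cumhaz(m, times = 8)), 1)
  expect_equal(as.numeric(excess_cumhaz(m, times = 80)),
               as.numeric(excess_cumhaz(m, times = 8)))
  expect_equal(cure_fraction(m)$pi, exp(-1))

  # the published cure-model constant reproduces the overall cure fraction
  m2 <- new_cure_model(knots = log(c(0.1, 1, 8)), gamma = c(-0.306, -0.2, -0.1))
  expect_equal(cure_fraction(m2)$pi, exp(-exp(-0.306)), tolerance = 1e-12)
  expect_equal(cure_fraction(m2)$pi, 0.4788, tolerance = 1e-4)
})

test_that("relative survival decreases from 1 to the cure fraction", {
  m <- toy_model()
  nd <- data.frame(size_cm = 3)
  tt <- c(0, 10^seq(-3, log10(30), length.out = 120))
  R <- as.numeric(relative_survival(m, nd, times = tt))
  expect_equal(R[1], 1)
  expect_true(all(diff(R) <= 1e-12))
  pi <- cure_fraction(m, nd)$pi
  expect_true(all(R >= pi - 1e-12))
  expect_equal(R[length(R)], pi)

  # monotone in a positive covariate effect: larger size, larger Lambda
  small <- as.numeric(excess_cumhaz(m, data.frame(size_cm = 1), times = tt[-1]))
  large <- as.numeric(excess_cumhaz(m, data.frame(size_cm = 4), times = tt[-1]))
  expect_true(all(large > small))
})

test_that("cure fraction respects the link limits", {
  lo <- new_cure_model(knots = log(c(0.1, 8)), gamma = c(20, -0.1))
  hi <- new_cure_model(knots = log(c(0.1, 8)), gamma = c(-20, -0.1))
  expect_equal(cure_fraction(lo)$pi, 0, tolerance = 1e-8)
  expect_equal(cure_fraction(hi)$pi, 1, tolerance = 1e-8)
})

test_that("closed-form relative survival matches numerical integration of the hazard", {
  m <- toy_model()
  nd <- data.frame(size_cm = 2.5)
  Lam <- function(u) as.numeric(excess_cumhaz(m, nd, times = u))
  # hazard mass per unit log time, lambda(e^s) e^s, via central differences;
  # integrating over s = log u avoids the integrable singularity at u = 0
  dLam_dlog <- function(s) {
    h <- 1e-5
    (vapply(s, function(x) Lam(exp(x + h)), 1) -
       vapply(s, function(x) Lam(exp(x - h)), 1)) / (2 * h)
  }
  for (t1 in c(0.5, 2, 5, 9, 11)) {
    num <- integrate(dLam_dlog, -30, log(t1), rel.tol = 1e-10,
                     subdivisions = 1000)$value
    expect_equal(exp(-num), as.numeric(relative_survival(m, nd, times = t1)),
                 tolerance = 1e-6)
  }
})

test_that("the fitter recovers a cure fraction with zero background mortality", {
  # mixture with pi = 0.35, exponential excess events, no background deaths
  dat <- sim_mixture_nobg(n = 1500, pi = 0.35, shape = 1, scale = 1, seed = 31)
  fit <- cure_model(Surv(t, d) ~ 1, dat, zero_lifetable(), df = 3)
  pihat <- cure_fraction(fit)$pi
  expect_lt(abs(pihat - 0.35), 0.05)
  expect_true(cure_fraction(fit)$lower < pihat & pihat < cure_fraction(fit)$upper)
})

test_that("the maximised likelihood dominates the generating parameters", {
  lt <- gompertz_lifetable(5e-5, 0.095)
  tm <- toy_model(lifetable = lt)
  set.seed(8)
  n <- 600
  nd <- data.frame(size_cm = rlnorm(n, log(2.5), 0.43),
                   age_years = runif(n, 45, 80),
                   sex = sample(c("male", "female"), n, TRUE),
                   year_ablation = sample(2004:2018, n, TRUE))
  sim <- simulate(tm, newdata = nd, censor_window = 15, seed = 9)
  dat <- cbind(nd, sim)
  fit <- cure_model(Surv(t, d) ~ size_cm, dat, lt, knots = tm$basis$knots)
  ll_truth <- manual_loglik(tm$basis$knots, tm$gamma, tm$beta,
                            as.matrix(dat["size_cm"]), dat$t, dat$d, lt,
                            dat$age_years, dat$sex, dat$year_ablation)
  expect_gte(fit$loglik, ll_truth - 1e-6)

  # and the estimate is close to the generating cure fraction
  expect_lt(abs(mean(cure_fraction(fit, nd)$pi) - mean(cure_fraction(tm, nd)$pi)),
            0.05)
})

test_that("rescaling a covariate rescales its coefficient inversely", {
  lt <- gompertz_lifetable(5e-5, 0.095)
  dat <- sim_mixture_nobg(n = 800, pi = 0.3, shape = 1.2, scale = 1.8, seed = 77)
  set.seed(78)
  dat$z <- rnorm(nrow(dat), 0, 1)
  dat$z2 <- 2 * dat$z
  k <- cure_basis_from_times(log(dat$t[dat$d == 1]), df = 3)$knots
  f1 <- cure_model(Surv(t, d) ~ z, dat, lt, knots = k)
  f2 <- cure_model(Surv(t, d) ~ z2, dat, lt, knots = k)
  expect_equal(unname(f2$beta), unname(f1$beta) / 2, tolerance = 1e-3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("an intercept-only simulated cohort recovers its cure fraction", {
  coefs <- c(constant = log(-log(0.30)), male = 0, year2014 = 0, hcv = 0,
             albi2 = 0, albi3 = 0, size_per_cm = 0, nodules_2_3 = 0,
             nodules_4plus = 0)
  sc <- simulate_cohort(sim_config(n = 3000, seed = 12, cure_coefs = coefs))
  expect_equal(unique(sc$truth$pi), 0.30)
  fit <- cure_model(Surv(t_dfs_years, d_dfs) ~ 1, sc$data, sc$lifetable)
  expect_lt(abs(cure_fraction(fit)$pi - 0.30), 0.04)
})

test_that("time to cure solves the conditional cure probability", {
  # analytic toy: Lambda(t) = 0.7 min(t, 10) / 10
  Ltoy <- function(t) 0.7 * pmin(t, 10) / 10
  t90 <- time_to_cure(Ltoy, certainty = 0.9, plateau_time = 10)
  expect_equal(t90, 10 * (1 - (-log(0.9)) / 0.7), tolerance = 1e-4)

  m <- toy_model()
  nd <- data.frame(size_cm = 2.5)
  pi <- cure_fraction(m, nd)$pi
  t1 <- time_to_cure(m, nd, certainty = pi + 0.01)
  expect_gt(t1, 0)
  # certainty already satisfied in the t -> 0 limit
  expect_equal(time_to_cure(m, nd, certainty = pi / 2), 0)
  # non-decreasing in certainty; certainty 1 hits the plateau onset
  certs <- c(0.5, 0.7, 0.9, 0.99, 1)
  ts <- vapply(certs, function(cc) time_to_cure(m, nd, certainty = cc), 1)
  expect_true(all(diff(ts) >= -1e-9))
  expect_equal(ts[length(ts)], exp(max(m$basis$knots)))

  # the conditional cure probability pi / R(t) is non-decreasing towards 1
  tt <- seq(0.01, 15, length.out = 300)
  ratio <- pi / as.numeric(relative_survival(m, nd, times = tt))
  expect_true(all(diff(ratio) >= -1e-12))
  expect_equal(ratio[length(ratio)], 1)
})

test_that("model methods behave", {
  lt <- gompertz_lifetable(5e-5, 0.095)
  dat <- sim_mixture_nobg(n = 500, pi = 0.3, shape = 1.2, scale = 1.8, seed = 5)
  set.seed(6)
  dat$size_cm <- rlnorm(nrow(dat), log(2.5), 0.4)
  fit <- cure_model(Surv(t, d) ~ size_cm, dat, lt, df = 3)

  expect_named(coef(fit), c("gamma0", "s1", "s2", "s3", "size_cm"))
  expect_equal(dim(vcov(fit)), c(5L, 5L))
  expect_s3_class(summary(fit), "summary.cure_model")
  expect_output(print(fit), "Cure fraction at reference")
  expect_equal(attr(logLik(fit), "df"), 5L)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))

  # predict() dispatch
  expect_equal(predict(fit, type = "cure")$pi, cure_fraction(fit)$pi)
  tt <- c(1, 5)
  expect_equal(predict(fit, dat[1:2, ], type = "relsurv", times = tt),
               relative_survival(fit, dat[1:2, ], times = tt))
  S <- predict(fit, dat[1, , drop = FALSE], type = "surv", times = tt)
  R <- as.numeric(relative_survival(fit, dat[1, , drop = FALSE], times = tt))
  expect_true(all(S < R))  # all-cause survival lies below net survival

  res <- residuals(fit)
  expect_length(res, nrow(dat))
  expect_true(all(is.finite(res)) && all(res <= 1))

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("prediction on newdata validates covariates", {
  m <- toy_model()
  expect_error(cure_fraction(m, data.frame(wrong = 1)), "lacks covariate")
})
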