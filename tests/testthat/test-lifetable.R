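test_that("life-table construction validates shape and rates", {
  ok <- lifetable(data.frame(sex = "male", age = 0:1, year = 2010,
                             rate = c(0.01, 0.02)))
  expect_s3_class(ok, "lifetable")
  expect_identical(dim(ok$rate), c(2L, 1L, 1L))

  expect_error(lifetable(data.frame(sex = "male", age = 0:1, year = 2010,
                                    rate = c(0.01, -0.01))), "non-negative")
  expect_error(lifetable(data.frame(sex = "male", age = c(0, 2), year = 2010,
                                    rate = 0.01)), "gap")
  expect_error(lifetable(data.frame(sex = "male", age = 0:1, rate = 0.01)),
               "missing column")
  expect_error(lifetable(data.frame(sex = "other", age = 0, year = 2010,
                                    rate = 0.01)), "unknown sex")

  big <- lifetable(expand.grid(sex = c("male", "female"), age = 0:100,
                               year = 2004:2019, rate = 0.02))
  expect_equal(max(big$ages), 100)
  expect_equal(range(big$years), c(2004, 2019))
})

test_that("CSV round trip preserves the table", {
  lt <- gompertz_lifetable(1e-4, 0.08, age_max = 30, years = 2010:2011,
                           population = "toy")
  path <- tempfile(fileext = ".csv")
  write_lifetable(lt, path)
  lt2 <- read_lifetable(path)
  expect_equal(lt2$rate, lt$rate)
  expect_identical(lt2$population, "toy")
  expect_error(read_lifetable(path, population = "nope"), "not found")
})

test_that("expected hazard follows the attained age and clamps at the edges", {
  lt <- const_lifetable(0.02)
  expect_equal(expected_hazard(lt, 50, "male", 2010, c(0, 3.7, 40)),
               rep(0.02, 3))

  g <- expand.grid(sex = "male", age = 0:110, year = 2000:2030)
  g$rate <- ifelse(g$age <= 60, 0.01, 0.03)
  step <- lifetable(g)
  expect_equal(expected_hazard(step, 60, "male", 2010, 1.5), 0.03)
  expect_equal(expected_hazard(step, 60, "male", 2010, 0.5), 0.01)
  # closure beyond the open age group
  expect_equal(expected_hazard(step, 115, "male", 2010, 0), 0.03)
  expect_error(expected_hazard(step, 60, "female", 2010, 1), "not present")
})

test_that("expected survival integrates the piecewise-constant hazard exactly", {
  lt <- const_lifetable(0.02)
  expect_equal(expected_survival(lt, 60, "male", 2010, 5), exp(-0.1))
  expect_equal(expected_survival(lt, 60, "male", 2010, 0), 1)

  # hand integration: 0.01 for the first year, 0.02 for the second
  g <- expand.grid(sex = "male", age = 0:110, year = 2000:2030)
  g$rate <- ifelse(g$age <= 60, 0.01, 0.02)
  step <- lifetable(g)
  expect_equal(expected_survival(step, 60, "male", 2010, 2), exp(-0.03))

  # fractional age at origin splits the first cell
  expect_equal(expected_survival(step, 60.5, "male", 2010.5, 1),
               exp(-(0.5 * 0.01 + 0.5 * 0.02)))

  # non-increasing in t, bounded in (0, 1]
  tt <- seq(0, 40, by = 0.37)
  S <- expected_survival(gompertz_lifetable(1e-4, 0.09), 55, "female", 2010, tt)
  expect_true(all(diff(S) <= 0))
  expect_true(all(S > 0 & S <= 1))
})

test_that("survival is path independent over any partition", {
  lt <- gompertz_lifetable(5e-5, 0.095)
  t_end <- 17.3
  S_direct <- expected_survival(lt, 61.4, "female", 2007, t_end)
  set.seed(42)
  cuts <- sort(c(0, runif(7, 0, t_end), t_end))
  S_at <- expected_survival(lt, 61.4, "female", 2007, cuts)
  prod_conditional <- prod(S_at[-1] / S_at[-length(S_at)])
  expect_equal(prod_conditional, S_direct, tolerance = 1e-12)
})

test_that("expected residual life matches closed forms and quadrature", {
  lt <- const_lifetable(0.05)
  expect_equal(expected_residual_life(lt, 60, "male", 2010, 10),
               (1 - exp(-0.5)) / 0.05)
  # converges to 1/mu for long horizons
  expect_equal(expected_residual_life(lt, 30, "male", 2010, 200), 20,
               tolerance = 0.01)
  # monotone non-decreasing in horizon
  e5 <- expected_residual_life(lt, 60, "male", 2010, 5)
  e9 <- expected_residual_life(lt, 60, "male", 2010, 9)
  expect_true(e9 >= e5)

  # two-step toy versus brute-force quadrature
  step <- step_lifetable(0.01, 0.06, age_cut = 65)
  e <- expected_residual_life(step, 62.3, "female", 2005, 30)
  expect_equal(e, oracle_residual_life(step, 62.3, "female", 2005, 30),
               tolerance = 1e-6)
})

test_that("death probabilities convert to rates", {
  expect_equal(prob_to_rate(1 - exp(-0.02)), 0.02)
  expect_error(prob_to_rate(1), "\\[0, 1\\)")
})
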