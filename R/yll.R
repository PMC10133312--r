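#' Model-based mean survival of a treated patient
#'
#' Integrates the all-cause survival implied by the cure model,
#' `S(t) = S*(t) R(t)`: the life-table expected survival of the matched
#' reference individual times the modelled relative survival. Up to the
#' spline plateau the integral is evaluated by composite trapezoid on a fine
#' grid (`step` years) with `S*` computed exactly; beyond the plateau
#' `R(t) = pi` is constant, so the tail contributes
#' `pi * int S*(t) dt`, accumulated analytically over the
#' piecewise-exponential life-table cells.
#'
#' @param object a fitted [cure_model()], or a function `Lambda(t)` giving
#'   the cumulative excess hazard.
#' @param ... further arguments passed to methods.
#' @return mean survival in years (one value per profile).
#' @seealso [years_of_life_lost()], [expected_residual_life()]
#' @export
model_mean_survival <- function(object, ...) UseMethod("model_mean_survival")

# shared integrator: relsurv_fn(t) vectorised, pi = plateau value
.mean_survival_integral <- function(lt, age, sex, year, relsurv_fn, pi,
                                    plateau_time, horizon, step) {
  t_in <- min(plateau_time, horizon)
  grid <- unique(sort(c(seq(0, t_in, by = step), t_in)))
  S <- exp(-.bg_cumhaz(lt, age, sex, year, grid)$H)
  R <- relsurv_fn(grid)
  f <- S * R
  head_part <- sum(diff(grid) * (f[-1] + f[-length(f)]) / 2)
  tail_part <- 0
  if (horizon > plateau_time) {
    before <- if (plateau_time > 0) {
      expected_residual_life(lt, age, sex, year, plateau_time)
    } else 0
    tail_part <- pi * (expected_residual_life(lt, age, sex, year, horizon) - before)
  }
  head_part + tail_part
}

.default_horizon <- function(age) min(120 - age, 100)

#' @rdname model_mean_survival
#' @param newdata data frame with the model covariates and the background
#'   columns (age, sex, calendar year) named in the fit's `bg`.
#' @param horizon integration cap in years; defaults per patient to
#'   `min(120 - age, 100)`.
#' @param step trapezoid step in years for the pre-plateau integral.
#' @export
model_mean_survival.cure_model <- function(object, newdata = NULL,
                                           horizon = NULL, step = 0.05, ...) {
  if (is.null(newdata)) stop("newdata with background columns is required")
  bg <- object$bg
  for (nm in c("age", "sex", "year")) {
    if (!bg[[nm]] %in% names(newdata)) {
      stop("newdata lacks background column '", bg[[nm]], "'")
    }
  }
  plateau <- exp(max(object$basis$knots))
  pis <- cure_fraction(object, newdata)$pi
  vapply(seq_len(nrow(newdata)), function(i) {
    nd <- newdata[i, , drop = FALSE]
    agei <- nd[[bg[["age"]]]]
    hi <- if (is.null(horizon)) .default_horizon(agei) else horizon
    if (hi <= 0) stop("horizon must be positive")
    .mean_survival_integral(
      object$lifetable, agei, nd[[bg[["sex"]]]], nd[[bg[["year"]]]],
      function(tt) as.numeric(relative_survival(object, nd, times = tt)),
      pis[i], plateau, hi, step)
  }, numeric(1))
}

#' @rdname model_mean_survival
#' @param lifetable a [lifetable()] (function method only).
#' @param age,sex,year reference-subject characteristics at the time origin
#'   (function method only).
#' @param plateau_time time at which `Lambda` has plateaued (function
#'   method only).
#' @export
model_mean_survival.function <- function(object, lifetable, age, sex, year,
                                         plateau_time, horizon = NULL,
                                         step = 0.05, ...) {
  hi <- if (is.null(horizon)) .default_horizon(age) else horizon
  if (hi <= 0) stop("horizon must be positive")
  pi <- exp(-object(plateau_time)[1L])
  .mean_survival_integral(lifetable, age, sex, year,
                          function(tt) exp(-object(tt)), pi,
                          plateau_time, hi, step)
}

#' Years of life lost (loss in expectation of life)
#'
#' The difference between the mean residual life of a matched individual of
#' the reference population (from the life table) and the model-based mean
#' survival of the treated patient, both integrated to the same horizon:
#' `yll = e_ref - e_model`.
#'
#' @inheritParams model_mean_survival
#' @return data frame with one row per profile and columns `e_ref`,
#'   `e_model` and `yll` (all in years).
#' @export
years_of_life_lost <- function(object, ...) UseMethod("years_of_life_lost")

#' @rdname years_of_life_lost
#' @export
years_of_life_lost.cure_model <- function(object, newdata = NULL,
                                          horizon = NULL, step = 0.05, ...) {
  if (is.null(newdata)) stop("newdata with background columns is required")
  bg <- object$bg
  e_model <- model_mean_survival(object, newdata, horizon = horizon, step = step)
  e_ref <- vapply(seq_len(nrow(newdata)), function(i) {
    agei <- newdata[[bg[["age"]]]][i]
    hi <- if (is.null(horizon)) .default_horizon(agei) else horizon
    expected_residual_life(object$lifetable, agei, newdata[[bg[["sex"]]]][i],
                           newdata[[bg[["year"]]]][i], hi)
  }, numeric(1))
  data.frame(e_ref = e_ref, e_model = e_model, yll = e_ref - e_model)
}

#' @rdname years_of_life_lost
#' @export
years_of_life_lost.function <- function(object, lifetable, age, sex, year,
                                        plateau_time, horizon = NULL,
                                        step = 0.05, ...) {
  hi <- if (is.null(horizon)) .default_horizon(age) else horizon
  e_model <- model_mean_survival(object, lifetable, age, sex, year,
                                 plateau_time, horizon = hi, step = step)
  e_ref <- expected_residual_life(lifetable, age, sex, year, hi)
  data.frame(e_ref = e_ref, e_model = e_model, yll = e_ref - e_model)
}

#' Linear (GLM) approximation of years of life lost
#'
#' Re-fits model-based per-patient YLL predictions with an identity-link
#' Gaussian linear model, yielding a bedside additive approximation
#' `yll ~ constant + sum(x * b)` and its goodness of fit
#' `R^2 = 1 - SSE/SST`.
#'
#' @param yll numeric vector of per-patient YLL predictions.
#' @param data data frame of covariates (including age in years) to regress
#'   on; all columns are used.
#' @return An object of class `yll_approx`: list with `coefficients`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
refit_yll_glm <- function(yll, data) {
  if (!is.data.frame(data)) data <- as.data.frame(data)
  if (length(yll) != nrow(data)) stop("yll and data lengths differ")
  if (length(yll) < ncol(data) + 2L) stop("need at least p + 2 observations")
  df <- cbind(.yll = yll, data)
  fit <- stats::lm(.yll ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient YLL design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((yll - mean(yll))^2)
  structure(list(coefficients = stats::coef(fit),
                 r_squared = 1 - sse / sst,
                 model = fit),
            class = "yll_approx")
}

#' @export
print.yll_approx <- function(x, digits = 4, ...) {
  cat("Linear approximation of years of life lost (OLS, identity link)\n")
  cat("R-squared:", format(x$r_squared, digits = digits), "\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
predict.yll_approx <- function(object, newdata, ...) {
  unname(stats::predict(object$model, newdata = newdata))
}
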