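#' Flexible parametric non-mixture cure model on the relative-survival scale
#'
#' Fits a spline-based non-mixture cure model for disease-free survival of a
#' cancer cohort relative to the background mortality of a matched general
#' population. The log cumulative excess hazard is
#' \deqn{\log \Lambda(t \mid x) = \gamma_0 + \sum_j \gamma_j v_j(\log t) + x^\top \beta,}
#' where the `v_j` form a cure-constrained spline basis ([cure_basis()]):
#' every `v_j` is exactly zero at and beyond the last knot, so the cumulative
#' excess hazard plateaus and the relative survival
#' `R(t | x) = exp(-Lambda(t | x))` flattens at the cure fraction
#' \deqn{\pi(x) = \exp(-\exp(\gamma_0 + x^\top \beta)).}
#'
#' Estimation maximises the relative-survival log likelihood
#' \deqn{\ell = \sum_i d_i \log\{h^*_i(t_i) + \lambda_i(t_i)\} - \Lambda_i(t_i),}
#' where `h*_i` is the life-table hazard at subject `i`'s attained age and
#' calendar year at `t_i` and `lambda = dLambda/dt` is the excess hazard
#' (terms in `log S*` that do not involve parameters are dropped).
#' Optimisation is quasi-Newton (BFGS) with analytic gradients, multi-started
#' over an intercept grid; the covariance is the inverse observed
#' information.
#'
#' @param formula a formula with a [survival::Surv()] response giving
#'   disease-free survival time in years (`> 0`) and the event indicator,
#'   and covariate terms entering the cure linear predictor proportionally.
#' @param data data frame holding the model covariates and the background
#'   lookup columns named in `bg`.
#' @param lifetable a [lifetable()] with the reference-population mortality.
#' @param bg named character vector mapping `age`, `sex` and `year` to
#'   columns of `data` (age at ablation in years, sex as
#'   `"male"`/`"female"`, calendar year at ablation).
#' @param df spline degrees of freedom; `df + 1` knots are placed at equally
#'   spaced centiles of the log uncensored event times.
#' @param knots optional explicit log-time knots overriding `df`.
#' @param starts intercept grid for multi-start optimisation.
#' @param control passed to [stats::optim()] (`reltol` defaults to `1e-8`).
#' @return An object of class `cure_model` with methods `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `confint`, `predict`, `residuals`, `plot` and
#'   `simulate`, and the fields `coefficients`, `basis`, `vcov`, `loglik`,
#'   `n`, `n_events`.
#' @seealso [cure_fraction()], [relative_survival()], [time_to_cure()],
#'   [years_of_life_lost()], [select_cure_model()]
#' @importFrom survival Surv survfit
#' @examples
#' lt <- gompertz_lifetable(a = 5e-5, b = 0.095)
#' cohort <- simulate_cohort(sim_config(n = 400, seed = 7), lt)
#' fit <- cure_model(survival::Surv(t_dfs_years, d_dfs) ~ size_cm,
#'                   data = cohort$data, lifetable = lt,
#'                   bg = c(age = "age_years", sex = "sex", year = "year_ablation"),
#'                   df = 2)
#' cure_fraction(fit)
#' @export
cure_model <- function(formula, data, lifetable,
                       bg = c(age = "age_years", sex = "sex", year = "year_ablation"),
                       df = 4, knots = NULL,
                       starts = c(-1, -0.5, 0, 0.5),
                       control = list()) {
  stopifnot(inherits(lifetable, "lifetable"))
  for (nm in c("age", "sex", "year")) {
    if (!nm %in% names(bg)) stop("`bg` must name an '", nm, "' column")
    if (!bg[[nm]] %in% names(data)) {
      stop("background column '", bg[[nm]], "' not found in `data`")
    }
  }
  cl <- match.call()

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("the response must be a survival::Surv object")
  t <- as.numeric(y[, 1L])
  d <- as.numeric(y[, 2L])
  if (any(t <= 0)) stop("disease-free survival times must be positive")
  if (!all(d %in% c(0, 1))) stop("event indicator must be 0/1")

  tt <- stats::terms(mf)
  Xfull <- stats::model.matrix(tt, mf)
  assign_full <- attr(Xfull, "assign")
  keep <- assign_full != 0L
  X <- Xfull[, keep, drop = FALSE]
  term_assign <- assign_full[keep]
  p <- ncol(X)

  age <- as.numeric(data[[bg[["age"]]]])
  sex <- as.character(data[[bg[["sex"]]]])
  year <- as.numeric(data[[bg[["year"]]]])

  # knots and basis from uncensored event times
  if (is.null(knots)) {
    basis <- cure_basis_from_times(log(t[d == 1]), df = df)
  } else {
    basis <- cure_basis(knots)
  }
  # rescale basis columns for conditioning (plateau value 0 is preserved)
  V0 <- cure_basis_matrix(basis, log(t))
  sc <- apply(V0, 2, stats::sd)
  sc[sc < 1e-12] <- 1
  basis <- cure_basis(basis$knots, scale = sc)

  fit <- .fit_cure_likelihood(t, d, X, basis, lifetable, age, sex, year,
                              starts = starts, control = control)

  out <- structure(
    list(coefficients = fit$par, basis = basis,
         gamma = unname(fit$par[seq_len(length(basis$knots))]),
         beta = if (p) fit$par[length(basis$knots) + seq_len(p)] else numeric(0),
         beta_names = colnames(X),
         vcov = fit$vcov, loglik = fit$loglik,
         n = length(t), n_events = sum(d),
         converged = fit$converged, starts_tried = fit$starts_tried,
         terms = tt, xlevels = stats::.getXlevels(tt, mf),
         contrasts = attr(Xfull, "contrasts"),
         term_assign = term_assign,
         lifetable = lifetable, bg = bg,
         model = list(t = t, d = d, X = X, age = age, sex = sex, year = year),
         call = cl),
    class = "cure_model"
  )
  out
}

## ---- likelihood machinery ------------------------------------------------

# Log with a linear extension below eps: keeps the objective finite and C1
# when the total hazard at an event dips to (or below) zero during
# optimisation, while the gradient still pushes back into the valid region.
.safe_log <- function(x, eps = 1e-8) {
  ifelse(x >= eps, log(pmax(x, eps)), log(eps) + x / eps - 1)
}
.safe_log_grad <- function(x, eps = 1e-8) {
  ifelse(x >= eps, 1 / pmax(x, eps), 1 / eps)
}

.fit_cure_likelihood <- function(t, d, X, basis, lt, age, sex, year,
                                 starts = c(-1, -0.5, 0, 0.5),
                                 control = list()) {
  K <- length(basis$knots)
  p <- ncol(X)
  npar <- K + p
  xlog <- log(t)
  V <- cure_basis_matrix(basis, xlog)
  Vp <- cure_basis_deriv(basis, xlog)
  hstar <- expected_hazard(lt, age, sex, year, t)
  ev <- d == 1

  negll <- function(par) {
    g0 <- par[1L]
    gs <- par[1L + seq_len(K - 1L)]
    eta <- g0 + drop(V %*% gs)
    if (p) eta <- eta + drop(X %*% par[K + seq_len(p)])
    Lam <- exp(eta)
    lam <- Lam * drop(Vp %*% gs) / t
    tot <- hstar + lam
    val <- sum(.safe_log(tot[ev])) - sum(Lam)
    if (!is.finite(val)) val <- -1e12
    -val
  }
  grad <- function(par) {
    g0 <- par[1L]
    gs <- par[1L + seq_len(K - 1L)]
    eta <- g0 + drop(V %*% gs)
    if (p) eta <- eta + drop(X %*% par[K + seq_len(p)])
    Lam <- exp(eta)
    sp <- drop(Vp %*% gs)
    lam <- Lam * sp / t
    tot <- hstar + lam
    w <- numeric(length(t))
    w[ev] <- .safe_log_grad(tot[ev])
    g <- numeric(length(par))
    # gamma_0
    g[1L] <- sum(w[ev] * lam[ev]) - sum(Lam)
    # spline coefficients
    for (j in seq_len(K - 1L)) {
      dlam <- lam * V[, j] + Lam * Vp[, j] / t
      g[1L + j] <- sum(w[ev] * dlam[ev]) - sum(Lam * V[, j])
    }
    # covariate coefficients
    if (p) {
      for (k in seq_len(p)) {
        g[K + k] <- sum(w[ev] * lam[ev] * X[ev, k]) - sum(Lam * X[, k])
      }
    }
    -g
  }

  # initial gamma by OLS of the log Nelson-Aalen-type cumulative hazard of
  # the observed DFS on the basis (crude, background included -- start only)
  init <- rep(0, npar)
  sf <- survival::survfit(survival::Surv(t, d) ~ 1)
  ok <- sf$n.event > 0 & sf$surv > 0 & sf$surv < 1
  if (sum(ok) >= K + 1L) {
    yy <- log(-log(sf$surv[ok]))
    Vev <- cure_basis_matrix(basis, log(sf$time[ok]))
    co <- tryCatch(stats::lm.fit(cbind(1, Vev), yy)$coefficients,
                   error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co))) init[seq_len(K)] <- co
  }

  ctrl <- utils::modifyList(list(maxit = 2000, reltol = 1e-8), control)
  start_list <- c(list(init),
                  lapply(starts, function(s) { ii <- init; ii[1L] <- s; ii }))
  best <- NULL
  trail <- data.frame(start = numeric(0), loglik = numeric(0),
                      convergence = integer(0))
  for (st in start_list) {
    res <- tryCatch(stats::optim(st, negll, grad, method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    if (is.null(res)) next
    trail <- rbind(trail, data.frame(start = st[1L], loglik = -res$value,
                                     convergence = res$convergence))
    if (res$convergence == 0 && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("cure model failed to converge from any start; trail:\n",
         paste(utils::capture.output(print(trail)), collapse = "\n"))
  }

  H <- tryCatch(stats::optimHess(best$par, negll, grad), error = function(e) NULL)
  vc <- NULL
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc))) {
      warning("observed information is singular; using a pseudo-inverse")
      vc <- MASS::ginv(H)
    }
  }
  par <- best$par
  nm <- c("gamma0", paste0("s", seq_len(K - 1L)), colnames(X))
  names(par) <- nm
  if (!is.null(vc)) dimnames(vc) <- list(nm, nm)
  list(par = par, vcov = vc, loglik = -best$value, converged = TRUE,
       starts_tried = trail)
}

## ---- prediction internals ------------------------------------------------

# covariate matrix (columns in beta order) for newdata; NULL newdata gives
# the reference profile (all covariates at 0 / reference level)
.predict_X <- function(fit, newdata) {
  p <- length(fit$beta)
  if (is.null(newdata)) return(matrix(0, 1L, p, dimnames = list(NULL, fit$beta_names)))
  if (!is.null(fit$terms)) {
    tt <- stats::delete.response(fit$terms)
    mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels,
                             na.action = stats::na.fail)
    X <- stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    miss <- setdiff(fit$beta_names, names(newdata))
    if (length(miss)) stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "))
    X <- as.matrix(as.data.frame(newdata)[fit$beta_names])
  }
  miss <- setdiff(fit$beta_names, colnames(X))
  if (length(miss)) stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "))
  X <- X[, fit$beta_names, drop = FALSE]
  rownames(X) <- NULL
  X
}

# plateau linear predictor eta(inf) = gamma0 + X beta
.eta_inf <- function(fit, X) {
  eta <- rep(fit$gamma[1L], nrow(X))
  if (length(fit$beta)) eta <- eta + drop(X %*% fit$beta)
  eta
}

#' Cumulative excess hazard, relative survival and cure fraction
#'
#' `excess_cumhaz()` evaluates `Lambda(t | x)`; it is non-decreasing in `t`
#' and constant beyond the spline plateau. `relative_survival()` returns
#' `R(t | x) = exp(-Lambda(t | x))`, which decreases from 1 and flattens at
#' the cure fraction. `cure_fraction()` returns the plateau
#' `pi(x) = exp(-exp(eta))` with a delta-method confidence interval computed
#' on the log(-log) scale.
#'
#' @param fit a fitted [cure_model()] (or one built with [new_cure_model()]).
#' @param newdata data frame of covariate profiles; `NULL` means the
#'   reference profile (every covariate at 0 / its reference level).
#' @param times evaluation times in years.
#' @param level confidence level for `cure_fraction()`.
#' @return `excess_cumhaz()`/`relative_survival()`: a matrix with one row
#'   per profile and one column per time (dropped to a vector for a single
#'   profile). `cure_fraction()`: a data frame with columns `pi`, `lower`,
#'   `upper` and `eta`.
#' @export
excess_cumhaz <- function(fit, newdata = NULL, times) {
  stopifnot(inherits(fit, "cure_model"))
  if (any(times < 0)) stop("times must be non-negative")
  X <- .predict_X(fit, newdata)
  gs <- fit$gamma[-1L]
  sp <- numeric(length(times))
  pos <- times > 0
  sp[pos] <- drop(cure_basis_matrix(fit$basis, log(times[pos])) %*% gs)
  eta0 <- .eta_inf(fit, X)
  out <- exp(outer(eta0, sp, `+`))
  out[, !pos] <- 0 # Lambda(0) = 0
  colnames(out) <- format(times, trim = TRUE)
  if (nrow(out) == 1L) drop(out) else out
}

#' @rdname excess_cumhaz
#' @export
relative_survival <- function(fit, newdata = NULL, times) {
  exp(-excess_cumhaz(fit, newdata, times))
}

#' @rdname excess_cumhaz
#' @export
cure_fraction <- function(fit, newdata = NULL, level = 0.95) {
  stopifnot(inherits(fit, "cure_model"))
  X <- .predict_X(fit, newdata)
  eta <- .eta_inf(fit, X)
  pi <- exp(-exp(eta))
  lower <- upper <- rep(NA_real_, length(eta))
  if (!is.null(fit$vcov)) {
    K <- length(fit$gamma)
    G <- cbind(1, matrix(0, nrow(X), K - 1L), X)
    se <- sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    # eta is log(-log pi): higher eta means lower cure fraction
    lower <- exp(-exp(eta + z * se))
    upper <- exp(-exp(eta - z * se))
  }
  data.frame(pi = pi, lower = lower, upper = upper, eta = eta)
}

#' Time to statistical cure
#'
#' The earliest time at which the conditional probability of being cured
#' given still disease-free, `pi / R(t) = exp(Lambda(t) - Lambda(inf))`,
#' reaches a certainty level. Solved by bisection to `tol` years; returns 0
#' when the certainty is already met as `t -> 0`, and the plateau onset time
#' `exp(k_K)` when `certainty = 1`.
#'
#' @param object a fitted [cure_model()], or a function `Lambda(t)` giving
#'   the cumulative excess hazard (vectorised over `t`).
#' @param certainty required conditional cure probability, in `(0, 1]`.
#' @param tol bisection tolerance in years.
#' @param ... further arguments passed to methods.
#' @return time in years (one value per covariate profile).
#' @examples
#' # piecewise-linear toy: Lambda(t) = 0.7 min(t, 10) / 10
#' time_to_cure(function(t) 0.7 * pmin(t, 10) / 10, certainty = 0.9,
#'              plateau_time = 10)
#' @export
time_to_cure <- function(object, ...) UseMethod("time_to_cure")

.ttc_solve <- function(Lfn, Linf, certainty, plateau_time, tol) {
  if (certainty <= 0 || certainty > 1) stop("certainty must be in (0, 1]")
  if (certainty == 1) return(plateau_time)
  target <- Linf + log(certainty)
  if (target <= 0) return(0) # already satisfied in the limit t -> 0
  lo <- min(1e-9, plateau_time / 1e6)
  hi <- plateau_time
  if (Lfn(lo) >= target) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (Lfn(mid) >= target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' @rdname time_to_cure
#' @param newdata covariate profiles (as in [cure_fraction()]).
#' @export
time_to_cure.cure_model <- function(object, newdata = NULL, certainty = 0.9,
                                    tol = 1e-6, ...) {
  X <- .predict_X(object, newdata)
  plateau <- exp(max(object$basis$knots))
  vapply(seq_len(nrow(X)), function(i) {
    nd <- if (is.null(newdata)) NULL else newdata[i, , drop = FALSE]
    Linf <- exp(.eta_inf(object, X[i, , drop = FALSE]))
    Lfn <- function(tt) as.numeric(excess_cumhaz(object, nd, times = tt))
    .ttc_solve(Lfn, Linf, certainty, plateau, tol)
  }, numeric(1))
}

#' @rdname time_to_cure
#' @param plateau_time time at which `Lambda` has reached its plateau.
#' @export
time_to_cure.function <- function(object, certainty = 0.9, plateau_time,
                                  tol = 1e-6, ...) {
  .ttc_solve(function(tt) object(tt)[1L], object(plateau_time)[1L],
             certainty, plateau_time, tol)
}

## ---- S3 methods ----------------------------------------------------------

#' @export
coef.cure_model <- function(object, ...) object$coefficients

#' @export
vcov.cure_model <- function(object, ...) object$vcov

#' @export
logLik.cure_model <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
confint.cure_model <- function(object, parm, level = 0.95, ...) {
  co <- object$coefficients
  if (missing(parm)) parm <- names(co)
  se <- sqrt(diag(object$vcov))[parm]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(co[parm] - z * se, co[parm] + z * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  out
}

#' @export
print.cure_model <- function(x, digits = 4, ...) {
  cat("Flexible parametric non-mixture cure model (relative survival)\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat("n =", x$n, " events =", x$n_events,
      " spline df =", length(x$basis$knots) - 1L, "\n")
  cat("Knots (log years):", format(x$basis$knots, digits = digits), "\n")
  cat("Log-likelihood:", format(x$loglik, digits = digits + 2), "\n\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cf <- cure_fraction(x)
  cat("\nCure fraction at reference covariates:",
      sprintf("%.1f%% (95%% CI %.1f-%.1f)", 100 * cf$pi, 100 * cf$lower,
              100 * cf$upper), "\n")
  invisible(x)
}

#' @export
summary.cure_model <- function(object, ...) {
  co <- object$coefficients
  se <- if (is.null(object$vcov)) rep(NA_real_, length(co)) else
    sqrt(pmax(diag(object$vcov), 0))
  z <- co / se
  tab <- cbind(Estimate = co, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(call = object$call, coefficients = tab,
              loglik = object$loglik, n = object$n,
              n_events = object$n_events, knots = object$basis$knots,
              cure = cure_fraction(object))
  class(out) <- "summary.cure_model"
  out
}

#' @export
print.summary.cure_model <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat("n =", x$n, " events =", x$n_events, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nLog-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  cat("Cure fraction at reference covariates:",
      sprintf("%.1f%% (95%% CI %.1f-%.1f)", 100 * x$cure$pi,
              100 * x$cure$lower, 100 * x$cure$upper), "\n")
  invisible(x)
}

#' @export
predict.cure_model <- function(object, newdata = NULL,
                               type = c("cure", "relsurv", "cumhaz", "surv",
                                        "time_to_cure", "mean_survival", "yll"),
                               times = NULL, certainty = 0.9, horizon = NULL,
                               ...) {
  type <- match.arg(type)
  switch(type,
    cure = cure_fraction(object, newdata),
    relsurv = relative_survival(object, newdata, times = times),
    cumhaz = excess_cumhaz(object, newdata, times = times),
    surv = {
      if (is.null(newdata)) stop("type = 'surv' needs newdata with background columns")
      R <- relative_survival(object, newdata, times = times)
      R <- matrix(R, nrow = nrow(newdata))
      bg <- object$bg
      for (i in seq_len(nrow(newdata))) {
        S <- expected_survival(object$lifetable, newdata[[bg[["age"]]]][i],
                               newdata[[bg[["sex"]]]][i],
                               newdata[[bg[["year"]]]][i], times)
        R[i, ] <- R[i, ] * S
      }
      if (nrow(R) == 1L) drop(R) else R
    },
    time_to_cure = time_to_cure(object, newdata, certainty = certainty),
    mean_survival = model_mean_survival(object, newdata, horizon = horizon),
    yll = years_of_life_lost(object, newdata, horizon = horizon)
  )
}

#' @export
residuals.cure_model <- function(object, type = c("martingale"), ...) {
  type <- match.arg(type)
  m <- object$model
  Lam <- vapply(seq_len(object$n), function(i) {
    as.numeric(exp(.eta_inf(object, m$X[i, , drop = FALSE]) +
                   drop(cure_basis_matrix(object$basis, log(m$t[i])) %*%
                        object$gamma[-1L])))
  }, numeric(1))
  Hstar <- vapply(seq_len(object$n), function(i) {
    .bg_cumhaz(object$lifetable, m$age[i], m$sex[i], m$year[i], m$t[i])$H
  }, numeric(1))
  m$d - (Hstar + Lam)
}

#' @export
plot.cure_model <- function(x, newdata = NULL, tmax = NULL, n_grid = 200,
                            xlab = "Years since ablation",
                            ylab = "Relative (net) disease-free survival",
                            ...) {
  plateau <- exp(max(x$basis$knots))
  if (is.null(tmax)) tmax <- 1.25 * plateau
  tt <- seq(1e-6, tmax, length.out = n_grid)
  R <- relative_survival(x, newdata, times = tt)
  R <- matrix(R, ncol = length(tt))
  graphics::matplot(tt, t(R), type = "l", lty = 1, ylim = c(0, 1),
                    xlab = xlab, ylab = ylab, ...)
  pi <- cure_fraction(x, newdata)$pi
  graphics::abline(h = pi, lty = 3, col = "grey40")
  graphics::abline(v = plateau, lty = 3, col = "grey70")
  invisible(x)
}

#' @export
simulate.cure_model <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                                censor_window = Inf, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) {
    m <- object$model
    X <- m$X; age <- m$age; sex <- m$sex; year <- m$year
  } else {
    X <- .predict_X(object, newdata)
    bg <- object$bg
    age <- newdata[[bg[["age"]]]]; sex <- newdata[[bg[["sex"]]]]
    year <- newdata[[bg[["year"]]]]
  }
  n <- nrow(X)
  one <- function() {
    t_obs <- numeric(n); d_obs <- integer(n)
    for (i in seq_len(n)) {
      cap <- max(1, 120 - age[i])
      U <- stats::runif(1)
      Sfun <- function(tt) {
        exp(-.bg_cumhaz(object$lifetable, age[i], sex[i], year[i], tt)$H) *
          as.numeric(relative_survival(object,
                                       if (is.null(newdata)) NULL else newdata[i, , drop = FALSE],
                                       times = tt))
      }
      if (Sfun(cap) > U) {
        T <- cap
      } else {
        lo <- 1e-9; hi <- cap
        while (hi - lo > 1e-6) {
          mid <- (lo + hi) / 2
          if (Sfun(mid) > U) lo <- mid else hi <- mid
        }
        T <- (lo + hi) / 2
      }
      C <- if (is.finite(censor_window)) stats::runif(1, 0, censor_window) else cap
      t_obs[i] <- min(T, C)
      d_obs[i] <- as.integer(T <= C && T < cap)
    }
    data.frame(t = t_obs, d = d_obs)
  }
  out <- lapply(seq_len(nsim), function(k) one())
  if (nsim == 1L) out[[1L]] else out
}
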