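#' Read a cohort table from CSV
#'
#' Expects one row per patient with at least `sex`, `age_years`,
#' `year_ablation`, `t_dfs_years` and `d_dfs`; clinical covariates
#' (`hbv`, `hcv`, `alcohol`, `size_cm`, `n_nodules_class`, `technique`,
#' `albumin_g_l`, `bilirubin_umol_l`, `albi_grade`) are carried through when
#' present. The ALBI grade is computed from albumin and bilirubin when
#' absent, and the derived indicator columns used by the model formulas
#' (`male`, `year2014`, `albi2`, `albi3`, `nodules_2_3`, `nodules_4plus`)
#' are added.
#'
#' @param path path to the CSV file.
#' @return data frame, one row per patient.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age_years", "year_ablation", "t_dfs_years", "d_dfs")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$t_dfs_years <= 0)) stop("t_dfs_years must be positive")
  if (!all(df$d_dfs %in% c(0, 1))) stop("d_dfs must be 0/1")
  if (is.null(df$albi_grade) &&
      all(c("albumin_g_l", "bilirubin_umol_l") %in% names(df))) {
    df$albi_grade <- albi(df$albumin_g_l, df$bilirubin_umol_l)$grade
  }
  df$male <- as.numeric(df$sex == "male")
  df$year2014 <- as.numeric(df$year_ablation >= 2014)
  if (!is.null(df$albi_grade)) {
    df$albi2 <- as.numeric(df$albi_grade == 2)
    df$albi3 <- as.numeric(df$albi_grade == 3)
  }
  if (!is.null(df$n_nodules_class)) {
    df$nodules_2_3 <- as.numeric(df$n_nodules_class %in% c("2-3", "2 or 3"))
    df$nodules_4plus <- as.numeric(df$n_nodules_class == "4+")
  }
  df
}

#' Assemble a cure model from known coefficients
#'
#' Builds a prediction-only `cure_model` object from explicit knots and
#' coefficients — e.g. published ones, or a fit restored from JSON. All
#' prediction functions ([cure_fraction()], [relative_survival()],
#' [time_to_cure()], [model_mean_survival()]) work on it; confidence
#' intervals need `vcov`.
#'
#' @param knots log-time knots of the cure spline basis.
#' @param gamma spline coefficients, intercept first (length `K`).
#' @param beta named covariate coefficients.
#' @param scale basis scale factors (default 1).
#' @param vcov optional covariance of `c(gamma, beta)`.
#' @param lifetable optional [lifetable()] enabling all-cause predictions.
#' @param bg background column mapping (as in [cure_model()]).
#' @param loglik,n,n_events optional fit metadata.
#' @return An object of class `cure_model` (without a formula/terms: pass
#'   `newdata` with numeric columns named like `beta`).
#' @export
new_cure_model <- function(knots, gamma, beta = numeric(0), scale = NULL,
                           vcov = NULL, lifetable = NULL,
                           bg = c(age = "age_years", sex = "sex",
                                  year = "year_ablation"),
                           loglik = NA_real_, n = NA_integer_,
                           n_events = NA_integer_) {
  basis <- cure_basis(knots, scale = scale)
  K <- length(knots)
  if (length(gamma) != K) stop("gamma must have length(knots) elements")
  if (length(beta) && is.null(names(beta))) stop("beta must be named")
  par <- c(gamma, beta)
  names(par) <- c("gamma0", paste0("s", seq_len(K - 1L)), names(beta))
  structure(
    list(coefficients = par, basis = basis, gamma = unname(gamma),
         beta = beta, beta_names = names(beta), vcov = vcov,
         loglik = loglik, n = n, n_events = n_events, converged = NA,
         terms = NULL, xlevels = NULL, contrasts = NULL, term_assign = NULL,
         lifetable = lifetable, bg = bg, model = NULL, call = NULL),
    class = "cure_model"
  )
}

#' Serialise a cure model to JSON and back
#'
#' Writes knots, basis scales, coefficients, the coefficient covariance
#' (row-major) and fit metadata; `read_cure_model()` reconstructs a
#' prediction-ready [new_cure_model()] (attach a life table separately for
#' all-cause predictions).
#'
#' @param fit a `cure_model`.
#' @param path JSON file path.
#' @return `write_cure_model()`: `path`, invisibly; `read_cure_model()`:
#'   a `cure_model`.
#' @export
write_cure_model <- function(fit, path) {
  stopifnot(inherits(fit, "cure_model"))
  obj <- list(
    format = "curablate_cure_model", version = 1L,
    knots = fit$basis$knots, scale = fit$basis$scale,
    gamma = unname(fit$gamma),
    beta = unname(fit$beta), covariates = fit$beta_names,
    vcov = if (is.null(fit$vcov)) NULL else as.numeric(t(fit$vcov)),
    loglik = fit$loglik, n = fit$n, n_events = fit$n_events
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cure_model
#' @export
read_cure_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "curablate_cure_model")) {
    stop("not a serialised cure model: ", path)
  }
  beta <- as.numeric(obj$beta)
  names(beta) <- obj$covariates
  npar <- length(obj$gamma) + length(beta)
  vc <- NULL
  if (!is.null(obj$vcov)) vc <- matrix(as.numeric(obj$vcov), npar, npar, byrow = TRUE)
  fit <- new_cure_model(knots = as.numeric(obj$knots),
                        gamma = as.numeric(obj$gamma), beta = beta,
                        scale = as.numeric(obj$scale), vcov = vc,
                        loglik = obj$loglik, n = obj$n, n_events = obj$n_events)
  nm <- names(fit$coefficients)
  if (!is.null(vc)) dimnames(fit$vcov) <- list(nm, nm)
  fit
}
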