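#' Published coefficient sets of the ablation bedside calculator
#'
#' Returns the multivariable coefficient sets of the HCC-ablation cure
#' calculator: the cure-probability set (log(-log) scale; cure probability
#' `exp(-exp(constant + sum(x * b)))`) and the YLL-approximation set
#' (identity link; `constant + sum(x * b)` years), together with the cohort
#' means used to impute covariates absent from a profile. Reference
#' categories (female, year < 2014, seronegative, ALBI 1, single nodule)
#' contribute 0.
#'
#' @return list with elements `cure`, `yll` (named coefficient vectors) and
#'   `cohort_means`.
#' @seealso [cure_probability()], [yll_approximation()]
#' @export
calculator_coefficients <- function() {
  list(
    cure = c(constant = -0.306, male = 0.166, year2014 = -0.141,
             hcv = 0.206, albi2 = 0.212, albi3 = 0.326,
             size_per_cm = 0.191, nodules_2_3 = 0.301, nodules_4plus = 0.812),
    yll = c(constant = 54.47, age_per_year = -0.653, male = -1.774,
            year2014 = -1.352, hbv = 0.286, hcv = 1.486,
            albi2 = 1.735, albi3 = 2.576, size_per_cm = 1.184,
            nodules_2_3 = 1.729, nodules_4plus = 3.846),
    cohort_means = c(hbv = 0.495, hcv = 0.229, male = 0.762, year2014 = 0.561)
  )
}

#' Patient profile for the bedside calculator
#'
#' Encodes one patient's clinical features as the numeric covariates of the
#' calculator. Features the calculator needs but the caller leaves at
#' `"mean"` are imputed with the cohort means bundled in
#' [calculator_coefficients()] (hepatitis B in particular, which enters only
#' the YLL equation).
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years age in years (used by the YLL equation only).
#' @param year calendar year of ablation, or directly `year2014 = TRUE/FALSE`.
#' @param year2014 logical, treated in 2014 or later.
#' @param hbv hepatitis B serology: 0, 1 or `"mean"`.
#' @param hcv hepatitis C serology: 0 or 1.
#' @param albi_grade ALBI grade 1, 2 or 3 (see [albi()]).
#' @param size_cm largest tumour diameter in cm, `> 0`.
#' @param nodules `"single"`, `"2-3"` or `"4+"`.
#' @return An object of class `patient_profile` (a named list of resolved
#'   numeric covariates).
#' @examples
#' p <- patient_profile(sex = "female", age_years = 55, year2014 = TRUE,
#'                      hcv = 0, albi_grade = 1, size_cm = 1.9,
#'                      nodules = "single")
#' cure_probability(p)
#' yll_approximation(p)
#' @export
patient_profile <- function(sex, age_years = NA_real_, year = NULL,
                            year2014 = NULL, hbv = "mean", hcv,
                            albi_grade, size_cm, nodules = "single") {
  sex <- match.arg(sex, c("male", "female"))
  if (!albi_grade %in% 1:3) stop("albi_grade must be 1, 2 or 3")
  if (size_cm <= 0) stop("size_cm must be positive")
  nodules <- match.arg(as.character(nodules), c("single", "2-3", "4+"))
  means <- calculator_coefficients()$cohort_means
  resolve <- function(x, nm) {
    if (identical(x, "mean")) return(unname(means[nm]))
    if (!x %in% 0:1) stop(nm, " must be 0, 1 or \"mean\"")
    as.numeric(x)
  }
  hbv <- resolve(hbv, "hbv")
  hcv <- resolve(hcv, "hcv")
  if (is.null(year2014)) {
    if (is.null(year)) stop("give either `year` or `year2014`")
    year2014 <- year >= 2014
  }
  structure(list(
    sex = sex, age_years = as.numeric(age_years),
    male = as.numeric(sex == "male"),
    year2014 = as.numeric(year2014),
    hbv = hbv, hcv = hcv,
    albi2 = as.numeric(albi_grade == 2), albi3 = as.numeric(albi_grade == 3),
    size_cm = as.numeric(size_cm),
    nodules_2_3 = as.numeric(nodules == "2-3"),
    nodules_4plus = as.numeric(nodules == "4+")
  ), class = "patient_profile")
}

.calc_linear <- function(p, co, need_age = FALSE) {
  eta <- co[["constant"]]
  if (need_age) {
    if (is.na(p$age_years)) stop("this equation needs age_years")
    eta <- eta + co[["age_per_year"]] * p$age_years
  }
  for (nm in setdiff(names(co), c("constant", "age_per_year", "size_per_cm"))) {
    eta <- eta + co[[nm]] * p[[nm]]
  }
  eta + co[["size_per_cm"]] * p$size_cm
}

#' Bedside cure probability and approximate years of life lost
#'
#' `cure_probability()` evaluates the published cure equation
#' `exp(-exp(constant + sum(x * b)))`; `yll_approximation()` evaluates the
#' additive YLL equation `constant + sum(x * b)` (years), clipped at 0 with
#' a warning since a negative loss of life is not meaningful.
#'
#' @param profile a [patient_profile()].
#' @param coefs coefficient sets, by default [calculator_coefficients()].
#' @return a probability in (0, 1), respectively years.
#' @export
cure_probability <- function(profile, coefs = calculator_coefficients()) {
  stopifnot(inherits(profile, "patient_profile"))
  exp(-exp(.calc_linear(profile, coefs$cure)))
}

#' @rdname cure_probability
#' @export
yll_approximation <- function(profile, coefs = calculator_coefficients()) {
  stopifnot(inherits(profile, "patient_profile"))
  yll <- .calc_linear(profile, coefs$yll, need_age = TRUE)
  if (yll < 0) {
    warning("negative approximated YLL clipped to 0")
    yll <- 0
  }
  yll
}

#' Percentile band of a cure probability or YLL value
#'
#' Classifies a value against the cohort's 25th/75th percentiles: cure
#' fraction 0.119 / 0.260, YLL 11.5 / 22.7 years. Bands are `low` below the
#' 25th percentile, `mid` from the 25th (inclusive) up to the 75th, and
#' `high` from the 75th percentile (inclusive) upward.
#'
#' @param value value(s) to classify.
#' @param kind `"cure"` or `"yll"`.
#' @return character vector of `"low"`, `"mid"`, `"high"`.
#' @export
classify_percentiles <- function(value, kind = c("cure", "yll")) {
  kind <- match.arg(kind)
  if (any(!is.finite(value))) stop("value must be finite")
  cuts <- switch(kind, cure = c(0.119, 0.260), yll = c(11.5, 22.7))
  ifelse(value < cuts[1], "low", ifelse(value < cuts[2], "mid", "high"))
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("Patient profile (", x$sex,
      if (!is.na(x$age_years)) paste0(", age ", x$age_years), ")\n", sep = "")
  v <- unlist(x[c("year2014", "hbv", "hcv", "albi2", "albi3", "size_cm",
                  "nodules_2_3", "nodules_4plus")])
  print(v)
  invisible(x)
}
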