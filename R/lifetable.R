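#' Life tables of background (expected) mortality
#'
#' A `lifetable` holds annual all-cause mortality rates of a reference
#' population, stratified by sex, integer age and calendar year, as published
#' in WHO-style national life tables. Rates are hazards per person-year (not
#' annual death probabilities; see [prob_to_rate()]). The table drives the
#' background component of relative-survival cure models: expected hazard,
#' expected survival along the age-by-calendar-year Lexis diagonal, and
#' expected residual life of a matched reference individual.
#'
#' @param data data frame with columns `sex` (`"male"`/`"female"`), `age`
#'   (integer years), `year` (integer calendar year) and `rate` (annual
#'   mortality rate per person-year). A `population` column is optional.
#' @param population label identifying the population the table refers to.
#' @return An object of class `lifetable` with fields `population`, `ages`,
#'   `years`, `sexes` and a rate array indexed `[age, year, sex]`.
#' @details Ages must form a contiguous range (per sex and year) and every
#'   (sex, year) stratum must be complete; rates must be finite and
#'   non-negative. Outside the tabulated age or year range lookups clamp to
#'   the nearest tabulated stratum (WHO tables end in an open age group).
#' @seealso [read_lifetable()], [gompertz_lifetable()], [expected_hazard()]
#' @examples
#' lt <- lifetable(expand.grid(sex = c("male", "female"), age = 0:5,
#'                             year = 2010, rate = 0.01))
#' expected_survival(lt, age = 2, sex = "male", year = 2010, t = 3)
#' @export
lifetable <- function(data, population = "population") {
  required <- c("sex", "age", "year", "rate")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("life table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data$sex <- as.character(data$sex)
  bad_sex <- setdiff(unique(data$sex), c("male", "female"))
  if (length(bad_sex)) {
    stop("unknown sex value(s) in life table: ", paste(bad_sex, collapse = ", "))
  }
  if (!is.numeric(data$rate) || anyNA(data$rate) || any(!is.finite(data$rate))) {
    stop("life-table rates must be finite numbers")
  }
  if (any(data$rate < 0)) stop("life-table rates must be non-negative")
  if (any(data$age != floor(data$age)) || any(data$year != floor(data$year))) {
    stop("life-table ages and years must be integers")
  }

  sexes <- sort(unique(data$sex))
  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  if (!identical(ages, seq(min(ages), max(ages)))) {
    stop("life-table ages must form a contiguous range; gap detected")
  }

  rate <- array(NA_real_, dim = c(length(ages), length(years), length(sexes)),
                dimnames = list(age = ages, year = years, sex = sexes))
  ia <- match(data$age, ages)
  iy <- match(data$year, years)
  is <- match(data$sex, sexes)
  if (anyDuplicated(cbind(ia, iy, is))) {
    stop("duplicated (sex, age, year) stratum in life table")
  }
  rate[cbind(ia, iy, is)] <- data$rate
  if (anyNA(rate)) {
    stop("incomplete life table: every (sex, year) stratum must cover all ages")
  }

  structure(
    list(population = population, ages = ages, years = years,
         sexes = sexes, rate = rate),
    class = "lifetable"
  )
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Life table: ", x$population, "\n", sep = "")
  cat("  sexes: ", paste(x$sexes, collapse = ", "), "\n", sep = "")
  cat("  ages:  ", min(x$ages), "-", max(x$ages), "\n", sep = "")
  cat("  years: ", min(x$years), "-", max(x$years), "\n", sep = "")
  cat("  rate range: [", format(min(x$rate), digits = 4), ", ",
      format(max(x$rate), digits = 4), "] per person-year\n", sep = "")
  invisible(x)
}

#' Read a life table from CSV
#'
#' Expects the columns `population,sex,age,year,rate` with rates per
#' person-year; one row per (population, sex, age, year) stratum.
#'
#' @param path path to the CSV file.
#' @param population which population to extract; defaults to the single
#'   population present, and is an error if the file holds several.
#' @return A [lifetable()].
#' @export
read_lifetable <- function(path, population = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("population", "sex", "age", "year", "rate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("life-table file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pops <- unique(df$population)
  if (is.null(population)) {
    if (length(pops) > 1L) {
      stop("file holds several populations (", paste(pops, collapse = ", "),
           "); pass `population`")
    }
    population <- pops
  }
  if (!population %in% pops) {
    stop("population '", population, "' not found in ", path)
  }
  lifetable(df[df$population == population, , drop = FALSE], population = population)
}

#' Write a life table to CSV
#' @param lt a [lifetable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  grid <- expand.grid(age = lt$ages, year = lt$years, sex = lt$sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- lt$rate[cbind(match(grid$age, lt$ages),
                             match(grid$year, lt$years),
                             match(grid$sex, lt$sexes))]
  out <- data.frame(population = lt$population, grid[c("sex", "age", "year", "rate")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert annual death probabilities to mortality rates
#'
#' Published life tables sometimes report the annual probability of death
#' `q` rather than a rate. Under a constant hazard within the year,
#' `mu = -log(1 - q)`.
#'
#' @param q annual death probabilities in `[0, 1)`.
#' @return rates per person-year.
#' @export
prob_to_rate <- function(q) {
  if (any(q < 0 | q >= 1)) stop("annual death probabilities must lie in [0, 1)")
  -log1p(-q)
}

## Clamped stratum indices for attained age / calendar year (closure rule:
## beyond the tabulated range the nearest stratum is used).
.lt_index <- function(lt, age, year, sex) {
  sex <- as.character(sex)
  bad <- !sex %in% lt$sexes
  if (any(bad)) stop("sex '", sex[bad][1], "' not present in life table")
  ia <- pmin(pmax(floor(age), min(lt$ages)), max(lt$ages)) - min(lt$ages) + 1L
  iy <- pmin(pmax(floor(year), min(lt$years)), max(lt$years)) - min(lt$years) + 1L
  cbind(ia, iy, match(sex, lt$sexes))
}

#' Background hazard, survival and residual life of a reference individual
#'
#' `expected_hazard()` returns the life-table mortality rate at the attained
#' age and attained calendar year of a reference subject `t` years after the
#' origin (age and year advance together along the Lexis diagonal).
#' `expected_survival()` integrates that piecewise-constant hazard exactly,
#' `S*(t) = exp(-int_0^t mu*(u) du)`, and `expected_residual_life()`
#' accumulates `int_0^horizon S*(t) dt` analytically over the
#' piecewise-exponential cells.
#'
#' @param lt a [lifetable()].
#' @param age age in years at the time origin; may be fractional.
#' @param sex `"male"` or `"female"`.
#' @param year calendar year at the time origin.
#' @param t time since origin in years (vectorised).
#' @param horizon integration cap in years (scalar, `> 0`).
#' @return `expected_hazard()`: rates per person-year; `expected_survival()`:
#'   probabilities; `expected_residual_life()`: years.
#' @examples
#' lt <- gompertz_lifetable(a = 5e-5, b = 0.095, years = 2010)
#' expected_hazard(lt, 60, "female", 2010, t = 0:5)
#' expected_survival(lt, 60, "female", 2010, t = c(1, 5, 10))
#' expected_residual_life(lt, 60, "female", 2010, horizon = 60)
#' @export
expected_hazard <- function(lt, age, sex, year, t) {
  stopifnot(inherits(lt, "lifetable"))
  if (any(t < 0)) stop("t must be non-negative")
  n <- max(length(age), length(sex), length(year), length(t))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  year <- rep_len(year, n); t <- rep_len(t, n)
  lt$rate[.lt_index(lt, age + t, year + t, sex)]
}

## Cell boundaries in t where the attained age or attained calendar year
## crosses an integer, so the hazard is constant within each segment.
.bg_breaks <- function(age, year, tmax) {
  if (tmax <= 0) return(c(0, 0))
  first_age <- ceiling(age + 1e-12) - age   # first integer-age crossing
  first_year <- ceiling(year + 1e-12) - year
  crossings <- function(first) {
    if (first > tmax) numeric(0) else seq(first, tmax, by = 1)
  }
  br <- c(crossings(first_age), crossings(first_year))
  br <- br[br > 1e-12 & br < tmax - 1e-12]
  sort(unique(c(0, br, tmax)))
}

## Cumulative background hazard H*(t) at each element of tvec (exact
## piecewise-constant integration). Returns a list with the segment grid so
## callers can reuse it.
.bg_cumhaz <- function(lt, age, sex, year, tvec) {
  tmax <- max(tvec)
  if (tmax <= 0) return(list(H = rep(0, length(tvec))))
  grid <- .bg_breaks(age, year, tmax)
  mid <- (grid[-length(grid)] + grid[-1]) / 2
  mu <- expected_hazard(lt, age, sex, year, mid)
  width <- diff(grid)
  Hgrid <- c(0, cumsum(mu * width))
  seg <- findInterval(tvec, grid, rightmost.closed = TRUE)
  seg <- pmin(seg, length(mu))
  H <- Hgrid[seg] + mu[seg] * (tvec - grid[seg])
  H[tvec <= 0] <- 0
  list(H = H, grid = grid, mu = mu, Hgrid = Hgrid)
}

#' @rdname expected_hazard
#' @export
expected_survival <- function(lt, age, sex, year, t) {
  stopifnot(inherits(lt, "lifetable"))
  if (any(t < 0)) stop("t must be non-negative")
  exp(-.bg_cumhaz(lt, age, sex, year, t)$H)
}

#' @rdname expected_hazard
#' @export
expected_residual_life <- function(lt, age, sex, year, horizon) {
  stopifnot(inherits(lt, "lifetable"), length(horizon) == 1L)
  if (horizon <= 0) stop("horizon must be positive")
  ch <- .bg_cumhaz(lt, age, sex, year, horizon)
  S_start <- exp(-ch$Hgrid[-length(ch$Hgrid)])
  width <- diff(ch$grid)
  mu <- ch$mu
  cell <- ifelse(mu > 0, S_start * (1 - exp(-mu * width)) / mu, S_start * width)
  sum(cell)
}

#' Build a Gompertz life table
#'
#' Synthetic background mortality with hazard `mu*(age) = a * exp(b * age)`,
#' optionally drifting over calendar time and scaled by sex. Useful for
#' simulation and testing; `b = 0` gives a constant-rate (exponential) table.
#'
#' @param a baseline hazard at age 0 (per person-year), `> 0`.
#' @param b log-hazard slope per year of age, `>= 0`.
#' @param age_max highest tabulated age.
#' @param years calendar years to tabulate.
#' @param sexes sexes to tabulate.
#' @param sex_adjust named multipliers applied to the hazard per sex.
#' @param drift multiplicative annual drift: rates are multiplied by
#'   `exp(drift * (year - min(years)))` (negative values model secular
#'   mortality decline).
#' @param population population label.
#' @return A [lifetable()].
#' @export
gompertz_lifetable <- function(a, b, age_max = 110, years = 2004:2019,
                               sexes = c("male", "female"),
                               sex_adjust = c(male = 1, female = 1),
                               drift = 0, population = "gompertz") {
  if (a <= 0) stop("a must be positive")
  if (b < 0) stop("b must be non-negative")
  grid <- expand.grid(sex = sexes, age = 0:age_max, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  adj <- sex_adjust[grid$sex]
  adj[is.na(adj)] <- 1
  grid$rate <- a * exp(b * grid$age) * exp(drift * (grid$year - min(years))) *
    as.numeric(adj)
  lifetable(grid, population = population)
}
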