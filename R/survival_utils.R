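#' Derive disease-free survival from an event history
#'
#' Disease-free survival runs from ablation to the earliest of recurrence,
#' death, hepatic resection / liver transplantation, or last follow-up.
#' Recurrence and death count as events; resection and transplantation are
#' censoring events, as is administrative end of follow-up. A recurrence or
#' death on the same day as a censoring event counts as an event.
#'
#' @param ablation_date,recurrence_date,death_date,resection_transplant_date,last_followup_date
#'   vectors of `Date`s (or numeric times in years); optional dates may be
#'   `NA` where the event did not occur. All dates must be on or after
#'   ablation, and last follow-up on or after every other date.
#' @return data frame with `t_years` (`days / 365.25` when dates are given)
#'   and `event` (0/1).
#' @export
derive_dfs <- function(ablation_date, recurrence_date = NULL, death_date = NULL,
                       resection_transplant_date = NULL, last_followup_date) {
  n <- length(ablation_date)
  to_years <- function(x) {
    if (is.null(x)) return(rep(NA_real_, n))
    if (inherits(x, "Date") || inherits(ablation_date, "Date")) {
      as.numeric(difftime(as.Date(x), as.Date(ablation_date), units = "days")) / 365.25
    } else {
      as.numeric(x) - as.numeric(ablation_date)
    }
  }
  rec <- to_years(recurrence_date)
  dth <- to_years(death_date)
  rtx <- to_years(resection_transplant_date)
  fup <- to_years(last_followup_date)
  if (anyNA(fup)) stop("last_followup_date is required for every subject")
  all_t <- cbind(rec, dth, rtx, fup)
  if (any(all_t < 0, na.rm = TRUE)) stop("dates before ablation are inconsistent")
  if (any(all_t > fup + 1e-9, na.rm = TRUE)) {
    stop("last follow-up must be on or after every other date")
  }
  t_event <- pmin(rec, dth, na.rm = TRUE)            # earliest event
  t_cens <- pmin(rtx, fup, na.rm = TRUE)             # earliest censoring
  t_event[is.na(t_event)] <- Inf
  t_years <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)             # ties resolve to event
  data.frame(t_years = t_years, event = event)
}

#' Albumin-bilirubin (ALBI) liver-function score and grade
#'
#' `score = -0.085 * albumin + 0.66 * log10(bilirubin)` with albumin in g/L
#' and bilirubin in micromol/L. Grade 1: score of -2.60 or lower; grade 2:
#' above -2.60 up to -1.39; grade 3: above -1.39 (cut-offs inclusive on
#' their lower edge).
#'
#' @param albumin_g_l serum albumin in g/L, `> 0`.
#' @param bilirubin_umol_l total bilirubin in micromol/L, `> 0`.
#' @return data frame with `score` and integer `grade` in 1..3.
#' @examples
#' albi(albumin_g_l = 40, bilirubin_umol_l = 16)  # grade 1
#' @export
albi <- function(albumin_g_l, bilirubin_umol_l) {
  if (any(albumin_g_l <= 0) || any(bilirubin_umol_l <= 0)) {
    stop("albumin and bilirubin must be positive")
  }
  score <- -0.085 * albumin_g_l + 0.66 * log10(bilirubin_umol_l)
  grade <- ifelse(score <= -2.60, 1L, ifelse(score <= -1.39, 2L, 3L))
  data.frame(score = score, grade = grade)
}

#' Kaplan-Meier estimate with Greenwood confidence intervals
#'
#' Product-limit estimator with pointwise confidence intervals on the
#' log(-log) scale (Greenwood variance), clipped to `[0, 1]`. The median is
#' read by the step convention: the first observed time at which the
#' estimate drops to 0.5 or below.
#'
#' @param time follow-up times, `> 0`.
#' @param event 0/1 event indicators.
#' @param conf_level confidence level.
#' @return An object of class `km_curve`: a list with a `curve` data frame
#'   (`time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`) and `median`.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95) {
  if (!length(time)) stop("empty input")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                      surv = sf$surv,
                      lower = pmin(pmax(sf$lower, 0), 1),
                      upper = pmin(pmax(sf$upper, 0), 1))
  med <- curve$time[curve$surv <= 0.5]
  structure(list(curve = curve,
                 median = if (length(med)) min(med) else NA_real_,
                 conf_level = conf_level, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, "\n")
  cat("Median survival:", format(x$median, digits = 4), "years\n")
  utils::head(x$curve, 10) |> print()
  if (nrow(x$curve) > 10) cat("... (", nrow(x$curve) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier estimator
#'
#' Kaplan-Meier with the event indicator complemented, so that censorings
#' become the "events": the median of this curve estimates the median
#' potential follow-up of the cohort.
#'
#' @inheritParams kaplan_meier
#' @return median follow-up in years.
#' @export
reverse_km_median_followup <- function(time, event) {
  kaplan_meier(time, 1 - event)$median
}

#' Cure-plausibility plateau check
#'
#' A cure model only makes sense when the survival curve flattens with the
#' passing of time. This heuristic compares the Nelson-Aalen cumulative
#' hazard increment rate over the last `tail_fraction` of follow-up with the
#' rate over the earlier part: the plateau is deemed plausible when the tail
#' rate is below `ratio` times the early rate. With fewer than `min_at_risk`
#' subjects still at risk at the start of the tail window, the check is
#' inconclusive. Thresholds are heuristics (the published criterion is
#' visual) and are configurable.
#'
#' @inheritParams kaplan_meier
#' @param tail_fraction fraction of the follow-up span treated as the tail.
#' @param ratio maximal tail/early hazard-rate ratio compatible with a
#'   plateau.
#' @param min_at_risk minimal number at risk at the start of the tail.
#' @return list with `status` (`"plausible"`, `"not_plausible"` or
#'   `"inconclusive"`), `tail_rate`, `early_rate` and `rate_ratio`.
#' @export
plateau_check <- function(time, event, tail_fraction = 0.25, ratio = 0.1,
                          min_at_risk = 3) {
  if (length(unique(time[event == 1])) <= 2) {
    stop("plateau check needs more than 2 distinct event times")
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  na_inc <- sf$n.event / sf$n.risk
  H <- cumsum(na_inc)
  tmax <- max(time)
  tcut <- (1 - tail_fraction) * tmax
  H_at <- function(tt) { i <- findInterval(tt, sf$time); if (i == 0) 0 else H[i] }
  at_risk_tail <- sum(time >= tcut)
  early_rate <- H_at(tcut) / tcut
  tail_rate <- (H_at(tmax) - H_at(tcut)) / (tmax - tcut)
  status <- if (at_risk_tail < min_at_risk) {
    "inconclusive"
  } else if (tail_rate < ratio * early_rate) {
    "plausible"
  } else {
    "not_plausible"
  }
  list(status = status, tail_rate = tail_rate, early_rate = early_rate,
       rate_ratio = tail_rate / early_rate, at_risk_tail = at_risk_tail,
       tail_window = c(tcut, tmax))
}
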