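#' Two-stage covariate selection for the cure model
#'
#' Mirrors the conventional epidemiological workflow: each candidate term is
#' first screened in a univariable cure model and kept when its (joint) Wald
#' p-value is below `enter`; the screened set is then reduced by backward
#' elimination until every retained term has p below `stay`. Multi-column
#' terms (factors) are tested jointly with a Wald chi-square on all their
#' columns.
#'
#' @inheritParams cure_model
#' @param enter univariable screening threshold (default 0.10).
#' @param stay backward-elimination retention threshold (default 0.05).
#' @return The final [cure_model()] fit with an extra element `selection`, a
#'   data frame recording every screening and elimination step with its
#'   p-value. When no candidate survives screening, an intercept-only fit is
#'   returned with a warning.
#' @seealso [cure_model()]
#' @export
select_cure_model <- function(formula, data, lifetable,
                              bg = c(age = "age_years", sex = "sex",
                                     year = "year_ablation"),
                              df = 4, enter = 0.10, stay = 0.05, ...) {
  if (enter <= 0 || enter >= 1 || stay <= 0 || stay >= 1) {
    stop("enter and stay must lie in (0, 1)")
  }
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  if (!length(labels)) stop("no candidate covariates in formula")
  resp <- formula[[2L]]

  trail <- data.frame(stage = character(0), term = character(0),
                      p = numeric(0), action = character(0),
                      stringsAsFactors = FALSE)

  # stage 1: univariable screen
  kept <- character(0)
  for (lab in labels) {
    f1 <- stats::as.formula(call("~", resp, str2lang(lab)))
    fit1 <- cure_model(f1, data, lifetable, bg = bg, df = df, ...)
    p1 <- min(.term_wald(fit1)$p)
    keep <- is.finite(p1) && p1 < enter
    trail <- rbind(trail, data.frame(stage = "screen", term = lab, p = p1,
                                     action = if (keep) "kept" else "dropped"))
    if (keep) kept <- c(kept, lab)
  }
  if (!length(kept)) {
    warning("no candidate passed the univariable screen; returning an intercept-only fit")
    f0 <- stats::as.formula(call("~", resp, 1))
    fit0 <- cure_model(f0, data, lifetable, bg = bg, df = df, ...)
    fit0$selection <- trail
    return(fit0)
  }

  # stage 2: backward elimination at `stay`
  current <- kept
  repeat {
    f <- stats::as.formula(call("~", resp, str2lang(paste(current, collapse = "+"))))
    fit <- cure_model(f, data, lifetable, bg = bg, df = df, ...)
    w <- .term_wald(fit)
    worst <- which.max(w$p)
    if (w$p[worst] < stay || length(current) == 0L) break
    trail <- rbind(trail, data.frame(stage = "backward", term = w$term[worst],
                                     p = w$p[worst], action = "removed"))
    current <- setdiff(current, w$term[worst])
    if (!length(current)) {
      warning("backward elimination removed every term; returning an intercept-only fit")
      f0 <- stats::as.formula(call("~", resp, 1))
      fit <- cure_model(f0, data, lifetable, bg = bg, df = df, ...)
      break
    }
  }
  if (length(current)) {
    w <- .term_wald(fit)
    trail <- rbind(trail, data.frame(stage = "final", term = w$term, p = w$p,
                                     action = "retained"))
  }
  fit$selection <- trail
  fit
}

# joint Wald chi-square per model term on the covariate block
.term_wald <- function(fit) {
  labels <- attr(fit$terms, "term.labels")
  K <- length(fit$gamma)
  out <- data.frame(term = labels, p = NA_real_, stringsAsFactors = FALSE)
  if (is.null(fit$vcov)) return(out)
  for (i in seq_along(labels)) {
    idx <- K + which(fit$term_assign == i)
    if (!length(idx)) next
    b <- fit$coefficients[idx]
    Vb <- fit$vcov[idx, idx, drop = FALSE]
    W <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
    out$p[i] <- stats::pchisq(W, df = length(idx), lower.tail = FALSE)
  }
  out
}
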