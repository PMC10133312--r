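#' Cure-constrained spline basis on the log-time scale
#'
#' Basis functions for the log cumulative excess hazard of a non-mixture
#' cure model. With knots `k_1 < ... < k_K` in log time, the basis spans
#' cubic splines of `x = log t` that are linear below `k_1` and exactly
#' constant (equal to 0) at and beyond the last knot `k_K`. The constant
#' plateau is what encodes statistical cure: once every basis function has
#' flattened, the log cumulative excess hazard — and hence the relative
#' survival — no longer changes, and the model intercept plus covariate
#' effects alone determine the cure fraction.
#'
#' Each of the `K - 1` basis functions is continuous with a continuous first
#' derivative, built from a truncated-power representation evaluated at
#' `u = min(x, k_K)` with the right-boundary slope removed:
#' `v_j(x) = [(u - k_j)_+^3 - (k_K - k_j)^3 - 3 (k_K - k_j)^2 (u - k_K)] / (k_K - k_1)^2`.
#'
#' @param knots numeric vector of at least 2 distinct knot positions in log
#'   time, in increasing order.
#' @param scale optional positive scale factors (length `K - 1`) dividing
#'   each basis column; used internally to condition the likelihood.
#' @return An object of class `cure_basis`.
#' @seealso [cure_basis_matrix()], [cure_basis_deriv()]
#' @examples
#' b <- cure_basis(log(c(0.1, 1, 5, 10)))
#' x <- log(c(0.5, 2, 10, 100))
#' cure_basis_matrix(b, x)      # rows at/after the last knot are zero
#' @export
cure_basis <- function(knots, scale = NULL) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L) stop("need at least 2 knots")
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be distinct and increasing")
  }
  K <- length(knots)
  if (is.null(scale)) scale <- rep(1, K - 1L)
  if (length(scale) != K - 1L || any(scale <= 0)) {
    stop("scale must hold ", K - 1L, " positive values")
  }
  structure(list(knots = knots, scale = scale), class = "cure_basis")
}

#' Knots from observed event times
#'
#' Places `df + 1` knots at equally spaced centiles (0, ..., 100) of the log
#' uncensored event times, the conventional choice for flexible parametric
#' survival models.
#'
#' @param log_event_times log of the uncensored event times.
#' @param df spline degrees of freedom (number of basis functions), `>= 1`.
#' @return A [cure_basis()] with unit scales.
#' @export
cure_basis_from_times <- function(log_event_times, df = 4) {
  if (df < 1) stop("df must be at least 1")
  u <- unique(log_event_times)
  if (length(u) < df + 1L) {
    stop("need at least df + 1 = ", df + 1L, " distinct event times, got ",
         length(u))
  }
  knots <- unname(stats::quantile(log_event_times, probs = seq(0, 1, length.out = df + 1L),
                                  type = 7))
  if (anyDuplicated(knots)) stop("tied knot centiles; reduce df")
  cure_basis(knots)
}

#' Evaluate the cure spline basis
#' @param basis a [cure_basis()].
#' @param x log-time values.
#' @return `cure_basis_matrix()`: matrix `length(x)` by `K - 1` of basis
#'   values; `cure_basis_deriv()`: matrix of derivatives with respect to `x`
#'   (exactly zero at and beyond the last knot).
#' @export
cure_basis_matrix <- function(basis, x) {
  k <- basis$knots
  K <- length(k)
  kK <- k[K]
  den <- (kK - k[1])^2
  u <- pmin(x, kK)
  out <- matrix(0, length(x), K - 1L)
  for (j in seq_len(K - 1L)) {
    dj <- kK - k[j]
    out[, j] <- (pmax(u - k[j], 0)^3 - dj^3 - 3 * dj^2 * (u - kK)) /
      (den * basis$scale[j])
  }
  colnames(out) <- paste0("s", seq_len(K - 1L))
  out
}

#' @rdname cure_basis_matrix
#' @export
cure_basis_deriv <- function(basis, x) {
  k <- basis$knots
  K <- length(k)
  kK <- k[K]
  den <- (kK - k[1])^2
  inside <- x < kK
  u <- pmin(x, kK)
  out <- matrix(0, length(x), K - 1L)
  for (j in seq_len(K - 1L)) {
    dj <- kK - k[j]
    out[, j] <- ifelse(inside,
                       (3 * pmax(u - k[j], 0)^2 - 3 * dj^2) / (den * basis$scale[j]),
                       0)
  }
  colnames(out) <- paste0("s", seq_len(K - 1L))
  out
}

#' @export
print.cure_basis <- function(x, ...) {
  cat("Cure-constrained spline basis\n")
  cat("  knots (log time):", format(x$knots, digits = 4), "\n")
  cat("  plateau onset:   t =", format(exp(max(x$knots)), digits = 4), "\n")
  invisible(x)
}
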