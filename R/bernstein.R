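#' Bernstein polynomial basis
#'
#' Defines a Bernstein polynomial basis of `order` functions (polynomial
#' degree `order - 1`) on a closed interval.  The basis is used to
#' parameterize the monotone transformation function of the outcome: a
#' smooth baseline log-odds function in `order` parameters replaces the
#' `k_max` category-specific intercepts of a classical proportional odds
#' model.
#'
#' @param order Integer number of basis functions, at least 2.  The default
#'   of 7 is a parsimonious choice that leaves the transformation enough
#'   flexibility for sum scores with dozens of categories.
#' @param interval Numeric vector `c(lo, hi)` with `lo < hi`; for an ordinal
#'   outcome on `0..k_max` this is `c(0, k_max)`.
#' @return An object of class `"bernstein_basis"` with elements `order` and
#'   `interval`.
#' @examples
#' b <- bernstein_basis(7, c(0, 50))
#' bernstein_row(25, b)
#' @export
bernstein_basis <- function(order = 7L, interval) {
  order <- as.integer(order)
  interval <- as.numeric(interval)
  if (length(order) != 1L || is.na(order) || order < 2L) {
    stop("'order' must be a single integer >= 2")
  }
  if (length(interval) != 2L || anyNA(interval) || interval[1L] >= interval[2L]) {
    stop("'interval' must be c(lo, hi) with lo < hi")
  }
  structure(list(order = order, interval = interval),
            class = "bernstein_basis")
}

#' @export
print.bernstein_basis <- function(x, ...) {
  cat(sprintf("Bernstein basis: %d functions (degree %d) on [%g, %g]\n",
              x$order, x$order - 1L, x$interval[1L], x$interval[2L]))
  invisible(x)
}

#' Evaluate the Bernstein basis
#'
#' Returns the values of all basis functions at the (affinely rescaled)
#' evaluation points.  The basis is a partition of unity: the values are
#' non-negative and sum to one at every point of the interval.
#'
#' @param y Numeric vector of evaluation points inside the basis interval.
#' @param basis A [bernstein_basis()] object.
#' @return For a single point, a numeric vector of length `order`; for
#'   several points, a matrix with one row per point.
#' @export
bernstein_row <- function(y, basis) {
  stopifnot(inherits(basis, "bernstein_basis"))
  lo <- basis$interval[1L]
  hi <- basis$interval[2L]
  if (any(!is.finite(y)) || any(y < lo - 1e-9) || any(y > hi + 1e-9)) {
    stop(sprintf("evaluation points must lie in [%g, %g]", lo, hi))
  }
  tt <- pmin(pmax((y - lo) / (hi - lo), 0), 1)
  d <- basis$order - 1L
  k <- 0:d
  out <- outer(tt, k, function(t, k) choose(d, k) * t^k * (1 - t)^(d - k))
  if (length(y) == 1L) drop(out) else out
}

#' Floor discretization of a real-valued argument
#'
#' The transformation function is a step-constant function of an underlying
#' real argument: the basis is always evaluated at the largest integer less
#' than or equal to `y`.
#'
#' @param y Numeric vector.
#' @return Integer-valued numeric vector `floor(y)`.
#' @export
floor_discretize <- function(y) {
  floor(y)
}
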