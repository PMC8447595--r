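## Local polynomial regression (LOESS) over running order.
##
## Implemented directly so that the neighbourhood rule is pinned: the window
## for each target point is the ceil(span * n) nearest neighbours by
## distance in x, weighted by the tricube kernel, with a local polynomial of
## degree 1 or 2 and no robustness iterations. Classical implementations
## differ in how they truncate the window, and drift correction needs a
## single, documented convention.

#' Tricube-weighted local polynomial fit
#'
#' Fits a LOESS curve to `y` over strictly increasing positions `x` and
#' returns the fit evaluated at each `x`. For every target point the
#' `ceil(span * n)` nearest neighbours form the window; weights are tricube
#' in the scaled distance to the farthest neighbour, and a weighted
#' polynomial of the requested degree is solved locally. A locally linear
#' (or quadratic) fit reproduces any globally linear (quadratic) signal
#' exactly, which anchors the drift-correction contract.
#'
#' @param x numeric, strictly increasing positions (e.g. run orders).
#' @param y numeric, observed log2 values at `x` (no `NA`).
#' @param span fraction of points in each local window, in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#' @return numeric vector of fitted values at `x`.
#' @export
fitLoess <- function(x, y, span = 0.75, degree = 2L) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  if (is.unsorted(x, strictly = TRUE))
    stop("x must be strictly increasing")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  n <- length(x)
  q <- ceiling(span * n)
  ## the tricube weight vanishes at the window edge, so keep enough interior
  ## points to identify the local polynomial
  q <- max(q, degree + 2L)
  q <- min(q, n)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    if (h == 0) {
      fitted[i] <- y[i]
      next
    }
    w <- pmax(1 - (d / h)^3, 0)^3
    use <- which(w > 0)
    z <- x[use] - x[i]
    X <- cbind(1, z)
    if (degree == 2L) X <- cbind(X, z^2)
    if (length(use) <= degree) {
      ## too few interior points: weighted mean fallback
      fitted[i] <- sum(w[use] * y[use]) / sum(w[use])
      next
    }
    fit <- stats::lm.wfit(X, y[use], w[use])
    b <- fit$coefficients[1]
    if (is.na(b)) b <- sum(w[use] * y[use]) / sum(w[use])
    fitted[i] <- b
  }
  fitted
}
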