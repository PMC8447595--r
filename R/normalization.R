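## Sample-wide normalization (workflow step 2).
##
## All three normalizers operate per sample on observed (non-NA) values only
## and preserve the missingness pattern exactly. The choice of method is
## deliberately the user's: heterogeneous cohorts may violate the
## "bulk proteome unchanged" assumption behind quantile normalization.

#' @rdname normalizeMedian
#' @export
setGeneric("normalizeMedian", function(x) standardGeneric("normalizeMedian"))

#' @rdname normalizeQuantile
#' @export
setGeneric("normalizeQuantile",
           function(x) standardGeneric("normalizeQuantile"))

#' @rdname normalizeZscore
#' @export
setGeneric("normalizeZscore", function(x) standardGeneric("normalizeZscore"))

.normalizeMedianMatrix <- function(m) {
  nobs <- colSums(!is.na(m))
  if (any(nobs == 0))
    stop("sample(s) with no observed values: ",
         paste(colnames(m)[nobs == 0], collapse = ", "))
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  sweep(m, 2, med - target, "-")
}

#' Median-centering normalization
#'
#' Shifts every sample so that all per-sample medians coincide. The common
#' target is the median of the per-sample medians, which preserves the
#' absolute log2 intensity scale (raw-scale quantities such as CVs stay
#' meaningful after unlogging). This is the "milder" normalization: only the
#' location of each sample's distribution is touched.
#'
#' @param x a [BatchExperiment-class] or numeric log2 matrix
#'   (features x samples).
#' @return object of the same class with all sample medians equal.
#' @export
setMethod("normalizeMedian", "matrix",
          function(x) .normalizeMedianMatrix(x))

#' @rdname normalizeMedian
setMethod("normalizeMedian", "BatchExperiment", function(x) {
  .updateIntensities(x, .normalizeMedianMatrix(intensityMatrix(x)),
                     "normalize_median")
})

.normalizeQuantileMatrix <- function(m) {
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  nobs <- colSums(!is.na(m))
  if (any(nobs < 2))
    stop("sample(s) with < 2 observed values: ",
         paste(colnames(m)[nobs < 2], collapse = ", "))
  grid_n <- max(nobs)
  p <- if (grid_n == 1) 0.5 else (seq_len(grid_n) - 1) / (grid_n - 1)
  ## reference = per-rank mean over the samples' interpolated quantile
  ## functions evaluated on the common grid
  qmat <- vapply(seq_len(ncol(m)), function(j) {
    v <- sort(m[, j], na.last = NA)
    k <- length(v)
    if (k == grid_n) v
    else stats::approx(x = (seq_len(k) - 1) / (k - 1), y = v, xout = p,
                       rule = 2)$y
  }, numeric(grid_n))
  ref <- rowMeans(qmat)
  out <- m
  for (j in seq_len(ncol(m))) {
    obs <- which(!is.na(m[, j]))
    k <- length(obs)
    f <- (rank(m[obs, j], ties.method = "average") - 1) / (k - 1)
    out[obs, j] <- stats::approx(x = p, y = ref, xout = f, rule = 2)$y
  }
  out
}

#' Quantile normalization with missing values
#'
#' Forces every sample's intensity distribution onto a common reference
#' distribution. On complete data this is the classical procedure: each
#' sample's sorted vector is replaced by the vector of per-rank cross-sample
#' means. With missing values, the reference is built as the per-rank mean of
#' the samples' linearly interpolated quantile functions on a common grid of
#' `max(n_observed)` points, and each observed value is mapped to the
#' reference quantile at its within-sample fractional rank (ties receive the
#' average rank). The classical method is defined only for complete matrices;
#' this interpolation extension is this package's pinned-down convention and
#' reduces exactly to the classical result when no value is missing.
#'
#' @inheritParams normalizeMedian
#' @return object of the same class; missing cells remain missing.
#' @export
setMethod("normalizeQuantile", "matrix",
          function(x) .normalizeQuantileMatrix(x))

#' @rdname normalizeQuantile
setMethod("normalizeQuantile", "BatchExperiment", function(x) {
  .updateIntensities(x, .normalizeQuantileMatrix(intensityMatrix(x)),
                     "normalize_quantile")
})

.normalizeZscoreMatrix <- function(m) {
  nobs <- colSums(!is.na(m))
  if (any(nobs < 2))
    stop("sample(s) with < 2 observed values: ",
         paste(colnames(m)[nobs < 2], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sdv == 0))
    stop("sample(s) with zero standard deviation: ",
         paste(colnames(m)[sdv == 0], collapse = ", "))
  sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
}

#' Z-score normalization
#'
#' Standardises each sample to mean 0 and standard deviation 1 over its
#' observed values (denominator `n - 1`). Unlike median centering this also
#' equalises sample variances; use it when boxplots show substantial spread
#' differences between samples.
#'
#' @inheritParams normalizeMedian
#' @return object of the same class.
#' @export
setMethod("normalizeZscore", "matrix",
          function(x) .normalizeZscoreMatrix(x))

#' @rdname normalizeZscore
setMethod("normalizeZscore", "BatchExperiment", function(x) {
  .updateIntensities(x, .normalizeZscoreMatrix(intensityMatrix(x)),
                     "normalize_zscore")
})
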