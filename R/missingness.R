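## Batch-coupled missingness machinery.
##
## Missingness in MS proteomics is often batch-specific; treating absent
## values as zeros (or any imputed constant) injects batch-correlated
## structure that inflates diagnostic batch metrics. Defaults everywhere
## are therefore no-imputation with complete-feature subsetting; imputation
## is opt-in, loud and mask-tracked.

#' Missingness per feature and batch
#'
#' Exact observed/possible counts per feature x batch, plus a per-feature
#' flag for batch-coupled missingness (the missing fraction differs across
#' batches by more than `flagMargin`).
#'
#' @param x a [BatchExperiment-class].
#' @param batchFactor declared batch factor.
#' @param flagMargin difference in per-batch missing fractions above which a
#'   feature is flagged as batch-coupled.
#' @return list with `table` (`feature_id`, `batch`, `n_observed`,
#'   `n_possible`, `fraction_missing`), `flagged` (feature ids) and
#'   `flagMargin`.
#' @export
missingnessByBatch <- function(x, batchFactor, flagMargin = 0.2) {
  batch <- .batchLevels(x, batchFactor)
  m <- intensityMatrix(x)
  levels_b <- unique(batch)
  tabs <- lapply(levels_b, function(b) {
    idx <- which(batch == b)
    nobs <- rowSums(!is.na(m[, idx, drop = FALSE]))
    data.frame(feature_id = rownames(m), batch = b, n_observed = nobs,
               n_possible = length(idx),
               fraction_missing = 1 - nobs / length(idx),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  fm <- matrix(tab$fraction_missing, nrow = nrow(m),
               dimnames = list(rownames(m), levels_b))
  spread <- apply(fm, 1, max) - apply(fm, 1, min)
  list(table = tab, flagged = rownames(m)[spread > flagMargin],
       flagMargin = flagMargin)
}

#' Filter features by completeness
#'
#' Retains features observed in at least `minFraction` of samples, either
#' overall or in EVERY batch (`scope = "per_batch"`; with any
#' `minFraction > 0` this guarantees the completeness precondition of
#' [combatAdjust()]).
#'
#' @param x a [BatchExperiment-class].
#' @param minFraction required observed fraction in `[0, 1]`.
#' @param scope `"overall"` or `"per_batch"`.
#' @param batchFactor required when `scope = "per_batch"`.
#' @return the filtered [BatchExperiment-class]; the number of removed
#'   features is reported as a message and recorded in the processing log.
#' @export
completenessFilter <- function(x, minFraction,
                               scope = c("overall", "per_batch"),
                               batchFactor = NULL) {
  scope <- match.arg(scope)
  stopifnot(minFraction >= 0, minFraction <= 1)
  m <- intensityMatrix(x)
  keep <- if (scope == "overall") {
    rowMeans(!is.na(m)) >= minFraction
  } else {
    if (is.null(batchFactor))
      stop("scope = 'per_batch' requires a batchFactor")
    batch <- .batchLevels(x, batchFactor)
    ok <- rep(TRUE, nrow(m))
    for (b in unique(batch)) {
      idx <- which(batch == b)
      ok <- ok & rowMeans(!is.na(m[, idx, drop = FALSE])) >= minFraction
    }
    ok
  }
  removed <- sum(!keep)
  message(removed, " feature(s) removed by completeness filter (",
          scope, " >= ", minFraction, ")")
  out <- x[keep, ]
  log <- metadata(out)$processing_log
  log[[length(log) + 1L]] <- list(stage = "completeness_filter",
                                  min_fraction = minFraction, scope = scope,
                                  n_removed = removed)
  metadata(out)$processing_log <- log
  out
}

#' Impute missing values (opt-in, mask-tracked)
#'
#' Fills every missing cell according to an explicit policy and records the
#' imputation mask as a logical `"imputed"` assay so downstream QC can
#' exclude imputed cells. Imputed values can introduce batch-specific bias
#' and skew every complete-matrix diagnostic; avoid imputation where
#' possible, or perform it only after batch correction.
#'
#' @param x a [BatchExperiment-class].
#' @param policy `"zero"` (log2 zeros), `"global_min"` (observed global
#'   minimum), `"feature_min"` (per-feature observed minimum; features with
#'   no observation fall back to the global minimum), or `"small_noise"`
#'   (uniform draws from one log2 unit below the global minimum).
#' @param seed required for `"small_noise"` (reproducibility).
#' @return the imputed [BatchExperiment-class] with the `"imputed"` mask
#'   assay. Observed values are never altered.
#' @export
imputeValues <- function(x, policy = c("zero", "global_min", "feature_min",
                                       "small_noise"), seed = NULL) {
  policy <- match.arg(policy)
  m <- intensityMatrix(x)
  mask <- is.na(m)
  warning("imputation (policy '", policy, "') fills ", sum(mask),
          " cells and can bias batch diagnostics; prefer no imputation, ",
          "or impute only after batch correction", call. = FALSE)
  gmin <- suppressWarnings(min(m, na.rm = TRUE))
  out <- m
  if (policy == "zero") {
    out[mask] <- 0
  } else if (policy == "global_min") {
    out[mask] <- gmin
  } else if (policy == "feature_min") {
    fmin <- suppressWarnings(apply(m, 1, min, na.rm = TRUE))
    fmin[!is.finite(fmin)] <- gmin
    idx <- which(mask, arr.ind = TRUE)
    out[idx] <- fmin[idx[, 1]]
  } else {
    if (is.null(seed))
      stop("policy 'small_noise' requires a seed")
    out[mask] <- .withSeed(seed,
                           stats::runif(sum(mask), gmin - 1, gmin))
  }
  y <- .updateIntensities(x, out, "impute",
                          list(policy = policy, n_imputed = sum(mask)))
  assay(y, "imputed") <- mask
  y
}
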