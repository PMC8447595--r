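## Feature-level batch effect correction (workflow step 4).
##
## Two-step procedure: continuous MS signal drift is removed first by
## fitting one LOESS curve per feature per batch over running order and
## subtracting it, then the residual discrete batch effect is removed by
## median/mean centering or empirical-Bayes adjustment. Normalization
## (step 2) is expected to have been applied beforehand.

#' Per-feature per-batch LOESS drift correction
#'
#' For every feature and every batch, fits a LOESS curve to the feature's
#' observed log2 intensities over running order and subtracts it, then
#' re-anchors at the feature-by-batch median of the observed values. The
#' re-anchoring leaves each batch at its own median level, so the residual
#' discrete batch effect can be removed by the subsequent centering step.
#' Feature-by-batch cells with fewer than `minPoints` observations are left
#' unchanged and recorded as fallbacks (their discrete correction still
#' happens in the second step).
#'
#' A warning is raised when any batch holds fewer than 25 samples: fitting a
#' curve (or estimating location/scale) in small batches risks
#' overcorrection.
#'
#' @param x a [BatchExperiment-class]; expected to be normalized already
#'   (warned, not enforced).
#' @param batchFactor name of the declared batch factor to correct.
#' @param span LOESS span in (0, 1]; smaller spans overfit and overcorrect,
#'   larger spans miss real trends — choose per dataset.
#' @param degree local polynomial degree (1 or 2).
#' @param minPoints minimum observed values per feature x batch for curve
#'   fitting.
#' @return list with elements `corrected` (a [BatchExperiment-class]),
#'   `fits` (`data.frame`: `feature_id`, `batch`, `run_order`, `fitted`,
#'   `n_points`, `span`) and `fallbacks` (`data.frame`: `feature_id`,
#'   `batch`, `n_points`).
#' @export
correctDrift <- function(x, batchFactor, span = 0.75, degree = 2L,
                         minPoints = 8L) {
  stopifnot(is(x, "BatchExperiment"))
  batch <- .batchLevels(x, batchFactor)
  m <- intensityMatrix(x)
  ro <- runOrder(x)
  if (anyDuplicated(ro)) stop("run_order must be unique")
  stages <- vapply(processingLog(x), `[[`, "", "stage")
  if (!any(grepl("^normalize", stages)))
    warning("input has no recorded normalization step; ",
            "drift correction is intended for normalized data")
  tab <- table(batch)
  if (any(tab < 25))
    warning("batch(es) with fewer than 25 samples (",
            paste(names(tab)[tab < 25], collapse = ", "),
            "): curve fitting in small batches risks overcorrection")
  out <- m
  fits <- vector("list", 0L)
  fallbacks <- list()
  batches <- unique(batch)
  for (b in batches) {
    sidx <- which(batch == b)
    ord <- sidx[order(ro[sidx])]
    xb <- as.numeric(ro[ord])
    for (g in seq_len(nrow(m))) {
      obs <- which(!is.na(m[g, ord]))
      n <- length(obs)
      if (n == 0) next
      if (n < minPoints) {
        fallbacks[[length(fallbacks) + 1L]] <-
          data.frame(feature_id = rownames(m)[g], batch = b, n_points = n,
                     stringsAsFactors = FALSE)
        next
      }
      y <- m[g, ord[obs]]
      f <- fitLoess(xb[obs], y, span = span, degree = degree)
      out[g, ord[obs]] <- y - f + stats::median(y)
      fits[[length(fits) + 1L]] <-
        data.frame(feature_id = rownames(m)[g], batch = b,
                   run_order = xb[obs], fitted = f, n_points = n,
                   span = span, stringsAsFactors = FALSE)
    }
  }
  corrected <- .updateIntensities(
    x, out, "correct_drift",
    list(batch_factor = batchFactor, span = span, degree = degree,
         min_points = minPoints, n_fallbacks = length(fallbacks)))
  list(
    corrected = corrected,
    fits = if (length(fits)) do.call(rbind, fits) else
      data.frame(feature_id = character(0), batch = character(0),
                 run_order = numeric(0), fitted = numeric(0),
                 n_points = integer(0), span = numeric(0)),
    fallbacks = if (length(fallbacks)) do.call(rbind, fallbacks) else
      data.frame(feature_id = character(0), batch = character(0),
                 n_points = integer(0))
  )
}

#' Discrete batch centering
#'
#' Removes the discrete (batch-wise constant) component of the batch effect
#' per feature: each observed value is shifted by the difference between the
#' feature's global statistic and its statistic in the sample's batch, so
#' after correction every per-feature per-batch median (or mean) equals the
#' feature's global one. Features absent from a batch are corrected only in
#' the batches where they are observed, which makes this method robust to
#' batch-specific missingness.
#'
#' @inheritParams correctDrift
#' @param stat `"median"` (default, robust) or `"mean"`.
#' @return a corrected [BatchExperiment-class].
#' @export
centerDiscrete <- function(x, batchFactor, stat = c("median", "mean")) {
  stopifnot(is(x, "BatchExperiment"))
  stat <- match.arg(stat)
  statf <- if (stat == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  batch <- .batchLevels(x, batchFactor)
  m <- intensityMatrix(x)
  if (nrow(m) == 0)
    return(.updateIntensities(x, m, "center_discrete",
                              list(batch_factor = batchFactor, stat = stat)))
  global <- apply(m, 1, statf)
  out <- m
  for (b in unique(batch)) {
    sidx <- which(batch == b)
    sub <- m[, sidx, drop = FALSE]
    bstat <- apply(sub, 1, function(v) {
      if (all(is.na(v))) NA_real_ else statf(v)
    })
    out[, sidx] <- sweep(sub, 1, bstat - global, "-")
  }
  .updateIntensities(x, out, "center_discrete",
                     list(batch_factor = batchFactor, stat = stat))
}

#' Two-step batch effect correction
#'
#' Runs the full correction: continuous drift removal ([correctDrift()])
#' followed by discrete correction ([centerDiscrete()] or [combatAdjust()]).
#' Both steps record their provenance in the processing log of the returned
#' object.
#'
#' @inheritParams correctDrift
#' @param discreteMethod `"median"`, `"mean"` or `"combat"` for the second
#'   step.
#' @param covariates optional biological factor names passed to
#'   [combatAdjust()] to protect group differences.
#' @return list with `corrected` (a [BatchExperiment-class]), `driftFits`,
#'   `fallbacks`, and `combatParams` (a [CombatParams-class], or `NULL` when
#'   the discrete step is centering).
#' @export
adjustTwoStep <- function(x, batchFactor, span = 0.75, degree = 2L,
                          minPoints = 8L,
                          discreteMethod = c("median", "mean", "combat"),
                          covariates = NULL) {
  discreteMethod <- match.arg(discreteMethod)
  step1 <- correctDrift(x, batchFactor, span = span, degree = degree,
                        minPoints = minPoints)
  if (discreteMethod == "combat") {
    step2 <- combatAdjust(step1$corrected, batchFactor,
                          covariates = covariates)
    list(corrected = step2$corrected, driftFits = step1$fits,
         fallbacks = step1$fallbacks, combatParams = step2$params)
  } else {
    corrected <- centerDiscrete(step1$corrected, batchFactor,
                                stat = discreteMethod)
    list(corrected = corrected, driftFits = step1$fits,
         fallbacks = step1$fallbacks, combatParams = NULL)
  }
}
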