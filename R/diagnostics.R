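## Diagnostics of batch structure (workflow steps 1 and 3).

#' Per-sample intensity summary in running order
#'
#' The first look at a new matrix: one row per sample, ordered by MS
#' acquisition rank, with the location statistic, quartiles and Tukey
#' outlier count of the sample's observed log2 intensities, plus the batch
#' levels for colouring. Plotting the statistic against run order reveals
#' signal drift; the quartiles give boxplot-style spread and outliers.
#'
#' @param x a [BatchExperiment-class].
#' @param stat `"mean"` or `"median"`.
#' @return `data.frame` sorted by `run_order` with columns `sample_id`,
#'   `run_order`, one column per declared batch factor, `n_observed`,
#'   `value` (the chosen statistic), `q1`, `median`, `q3`, `n_outliers`
#'   (observations beyond 1.5 x IQR of the sample's quartiles).
#' @export
sampleOrderSummary <- function(x, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  m <- intensityMatrix(x)
  ro <- runOrder(x)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j][!is.na(m[, j])]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    data.frame(
      sample_id = colnames(m)[j],
      run_order = ro[j],
      n_observed = length(v),
      value = if (stat == "mean") mean(v) else stats::median(v),
      q1 = q[1], median = q[2], q3 = q[3],
      n_outliers = sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  for (f in batchFactorNames(x)) out[[f]] <- sampleFactor(x, f)
  out <- out[order(out$run_order), ]
  rownames(out) <- NULL
  out
}

## complete-feature subsetting shared by PCA / clustering / PVCA
.completeFeatures <- function(m, missingPolicy = c("complete_features",
                                                   "error"),
                              context = "analysis") {
  missingPolicy <- match.arg(missingPolicy)
  complete <- rowSums(is.na(m)) == 0
  if (missingPolicy == "error" && !all(complete))
    stop(sum(!complete), " feature(s) have missing values; ", context,
         " needs a complete matrix (completenessFilter() or an explicit ",
         "imputation policy)")
  if (!any(complete))
    stop("no complete features; apply completenessFilter() with a lower ",
         "threshold or choose an explicit imputation policy")
  list(m = m[complete, , drop = FALSE], nDropped = sum(!complete))
}

#' Principal component scores of samples
#'
#' Feature-wise centered PCA of the samples over complete features.
#' Features with any missing value are discarded first (and their count
#' reported prominently): batch-specific missingness otherwise masquerades
#' as batch clustering. Variance fractions per component are reported for
#' axis labelling.
#'
#' @param x a [BatchExperiment-class].
#' @param nComponents number of components to return (default all).
#' @param missingPolicy `"complete_features"` (drop incomplete features,
#'   report the count) or `"error"`.
#' @param scaleFeatures logical, unit-scale features before the
#'   decomposition.
#' @return list with `scores` (samples x components), `varianceFraction`
#'   (per returned component, fractions of total variance), `featuresUsed`,
#'   `nFeaturesDropped`.
#' @export
pcaScores <- function(x, nComponents = NULL,
                      missingPolicy = c("complete_features", "error"),
                      scaleFeatures = FALSE) {
  m <- intensityMatrix(x)
  cf <- .completeFeatures(m, missingPolicy, "PCA")
  if (nrow(cf$m) < 2) stop("PCA needs >= 2 complete features")
  if (ncol(cf$m) < 3) stop("PCA needs >= 3 samples")
  if (cf$nDropped > 0)
    message(cf$nDropped, " feature(s) with missing values excluded from PCA")
  pc <- stats::prcomp(t(cf$m), center = TRUE, scale. = scaleFeatures)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(nComponents)) length(vf) else
    min(nComponents, length(vf))
  list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    varianceFraction = vf[seq_len(k)],
    featuresUsed = rownames(cf$m),
    nFeaturesDropped = cf$nDropped
  )
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples over complete features, with the
#' per-leaf annotation levels attached for factor colouring of the
#' dendrogram. Correlation distance is `1 - Pearson r`.
#'
#' @param x a [BatchExperiment-class].
#' @param distance `"euclidean"`, `"manhattan"` or `"correlation"`.
#' @param linkage `"complete"`, `"average"` or `"ward"` (Ward D2 on
#'   distances).
#' @inheritParams pcaScores
#' @return list of class `"DendrogramReport"` with `merge`, `height`,
#'   `order`, `labels`, `distance`, `linkage`, `leafAnnotation` (factor
#'   levels in leaf order) and the underlying `hclust` object.
#' @export
hierarchicalCluster <- function(x,
                                distance = c("euclidean", "manhattan",
                                             "correlation"),
                                linkage = c("complete", "average", "ward"),
                                missingPolicy = c("complete_features",
                                                  "error")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- intensityMatrix(x)
  cf <- .completeFeatures(m, missingPolicy, "hierarchical clustering")
  if (cf$nDropped > 0)
    message(cf$nDropped,
            " feature(s) with missing values excluded from clustering")
  d <- switch(distance,
    euclidean = stats::dist(t(cf$m), method = "euclidean"),
    manhattan = stats::dist(t(cf$m), method = "manhattan"),
    correlation = stats::as.dist(1 - stats::cor(cf$m))
  )
  hc <- stats::hclust(d, method = switch(linkage, complete = "complete",
                                         average = "average",
                                         ward = "ward.D2"))
  factors <- c(batchFactorNames(x), bioFactorNames(x))
  leafAnn <- data.frame(sample_id = hc$labels[hc$order],
                        stringsAsFactors = FALSE)
  for (f in factors) leafAnn[[f]] <- sampleFactor(x, f)[hc$order]
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels, distance = distance, linkage = linkage,
         leafAnnotation = leafAnn, hclust = hc,
         nFeaturesDropped = cf$nDropped),
    class = "DendrogramReport"
  )
}

#' @export
print.DendrogramReport <- function(x, ...) {
  cat(sprintf("DendrogramReport: %d samples, %s distance, %s linkage\n",
              length(x$labels), x$distance, x$linkage))
  invisible(x)
}

#' Feature-level intensity trends over running order
#'
#' Extracts the observed trajectory of selected features (typically
#' constant-amount spike-ins, whose apparent variation is purely technical)
#' for plotting against running order.
#'
#' @param x a [BatchExperiment-class].
#' @param featureIds character vector of features; unknown ids are an error.
#' @param spikeInsOnly if `TRUE`, use the features flagged `is_spike_in`
#'   instead of `featureIds`.
#' @return long `data.frame` (`feature_id`, `sample_id`, `run_order`, batch
#'   factor columns, `intensity`) sorted by feature then run order; missing
#'   measurements are omitted, never filled.
#' @export
featureTrend <- function(x, featureIds = NULL, spikeInsOnly = FALSE) {
  m <- intensityMatrix(x)
  if (spikeInsOnly) featureIds <- spikeInFeatures(x)
  unknown <- setdiff(featureIds, rownames(m))
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  if (!length(featureIds))
    stop("no features selected")
  ro <- runOrder(x)
  rows <- lapply(featureIds, function(g) {
    obs <- which(!is.na(m[g, ]))
    df <- data.frame(feature_id = g, sample_id = colnames(m)[obs],
                     run_order = ro[obs], intensity = m[g, obs],
                     stringsAsFactors = FALSE)
    df[order(df$run_order), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  for (f in batchFactorNames(x))
    out[[f]] <- sampleFactor(x, f)[out$sample_id]
  rownames(out) <- NULL
  out
}

#' Confounding report for two annotation factors
#'
#' Cross-tabulates the levels of two factors and quantifies their
#' association with Cramer's V. `V = 1` means the factors induce nested or
#' identical sample partitions and cannot be separated by any correction
#' (e.g. digestion batch vs MS batch in heavily structured acquisition
#' schedules); correct only one of them.
#'
#' @param x a [BatchExperiment-class].
#' @param factorX,factorY annotation column names.
#' @return list with `table` (contingency table), `cramersV` in `[0, 1]` and
#'   logical `fullyConfounded`.
#' @export
confoundingReport <- function(x, factorX, factorY) {
  fx <- sampleFactor(x, factorX)
  fy <- sampleFactor(x, factorY)
  tab <- table(fx, fy, dnn = c(factorX, factorY))
  v <- cramersV(tab)
  list(table = tab, cramersV = v, fullyConfounded = v >= 1 - 1e-10)
}

#' @rdname confoundingReport
#' @param tab a contingency table (matrix of counts).
#' @return `cramersV(tab)` returns the normalized association in `[0, 1]`.
#' @export
cramersV <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected, na.rm = TRUE)
  k <- min(nrow(tab), ncol(tab))
  if (k < 2) return(0)
  v <- sqrt(chi2 / (n * (k - 1)))
  min(v, 1)
}
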