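## Correlation- and CV-based quality control (workflow step 5).
##
## Proximity-based controls only: replicate and within-batch sample
## correlations, same-protein peptide correlations, and replicate CVs.
## "More significant hits after correction" is deliberately not a QC
## criterion here — it cannot distinguish signal from leakage.

## run expr with a temporary RNG state
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

.catSummary <- function(pairs) {
  cats <- unique(pairs$category)
  do.call(rbind, lapply(cats, function(cc) {
    r <- pairs$r[pairs$category == cc]
    data.frame(category = cc, n = length(r),
               q1 = stats::quantile(r, 0.25, names = FALSE),
               median = stats::median(r),
               q3 = stats::quantile(r, 0.75, names = FALSE),
               mean = mean(r), stringsAsFactors = FALSE)
  }))
}

#' Sample-wise correlation summary
#'
#' Pearson correlation of every sample pair over pairwise-complete features,
#' classified as `replicate` (same replicate group), `within_batch` (same
#' level of the batch factor) or `between_batch`. In healthy data the
#' replicate distribution sits clearly above the unrelated ones; a large
#' within-vs-between gap quantifies the batch effect and should shrink
#' after correction. Pairs sharing fewer than `minOverlap` observed
#' features are excluded and counted.
#'
#' @param x a [BatchExperiment-class].
#' @param batchFactor declared batch factor used for the
#'   within/between-batch split.
#' @param minOverlap minimum shared observed features per pair.
#' @return list of class `"CorrelationSummary"` with `pairs` (`data.frame`:
#'   `sample1`, `sample2`, `category`, `r`, `overlap`), `summary`
#'   (per-category count/quartiles/mean) and `nExcluded`.
#' @export
sampleCorrelationSummary <- function(x, batchFactor, minOverlap = 50) {
  m <- intensityMatrix(x)
  if (ncol(m) < 2) stop("need >= 2 samples")
  batch <- .batchLevels(x, batchFactor)
  reps <- replicateGroups(x)
  cmat <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  omat <- crossprod(!is.na(m))
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  pairs <- data.frame(
    sample1 = colnames(m)[idx[, 1]],
    sample2 = colnames(m)[idx[, 2]],
    r = cmat[idx], overlap = omat[idx],
    stringsAsFactors = FALSE
  )
  same_rep <- if (is.null(reps)) rep(FALSE, nrow(pairs)) else {
    r1 <- reps[pairs$sample1]; r2 <- reps[pairs$sample2]
    !is.na(r1) & !is.na(r2) & r1 == r2
  }
  same_batch <- batch[pairs$sample1] == batch[pairs$sample2]
  pairs$category <- ifelse(same_rep, "replicate",
                           ifelse(same_batch, "within_batch",
                                  "between_batch"))
  keep <- pairs$overlap >= minOverlap & !is.na(pairs$r)
  excluded <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs))
    stop("no sample pair reaches the overlap of ", minOverlap,
         " shared features")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, summary = .catSummary(pairs),
                 nExcluded = excluded, minOverlap = minOverlap),
            class = "CorrelationSummary")
}

#' @export
print.CorrelationSummary <- function(x, ...) {
  cat("CorrelationSummary (", nrow(x$pairs), " pairs, ",
      x$nExcluded, " excluded)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Peptide-pair correlation summary
#'
#' Pearson correlation across samples for feature pairs, split into
#' `same_protein` (identical protein id; expected positive — they quantify
#' the same molecule) and `different_protein` (expected near zero).
#' Residual technical structure such as shared signal drift inflates the
#' unrelated-pair correlations; successful correction moves their mean back
#' toward zero while the same-protein pairs stay high. All same-protein
#' pairs are used; unrelated pairs are subsampled to `maxPairs`.
#'
#' @param x a [BatchExperiment-class] with protein annotation.
#' @param maxPairs cap on the number of different-protein pairs.
#' @param seed RNG seed for the subsampling; required when subsampling
#'   happens (reproducibility).
#' @param minOverlap minimum shared observed samples for a pair.
#' @return list of class `"CorrelationSummary"` (categories `same_protein`,
#'   `different_protein`).
#' @export
peptideCorrelationSummary <- function(x, maxPairs = 5000, seed = NULL,
                                      minOverlap = 5) {
  prot <- proteinIds(x)
  if (is.null(prot)) stop("no protein annotation (rowData protein_id)")
  m <- intensityMatrix(x)
  tabp <- table(prot)
  if (!any(tabp >= 2))
    stop("no protein with >= 2 mapped peptides")

  same <- do.call(rbind, lapply(names(tabp)[tabp >= 2], function(p) {
    f <- names(prot)[prot == p]
    t(utils::combn(f, 2))
  }))
  n <- nrow(m)
  all_pairs_n <- n * (n - 1) / 2
  n_diff <- all_pairs_n - nrow(same)
  if (n_diff > maxPairs) {
    if (is.null(seed))
      stop("subsampling ", n_diff, " different-protein pairs to ", maxPairs,
           " requires a seed")
    diff_idx <- .withSeed(seed, {
      picked <- matrix(NA_integer_, 0, 2)
      while (nrow(picked) < maxPairs) {
        i <- sample.int(n, maxPairs, replace = TRUE)
        j <- sample.int(n, maxPairs, replace = TRUE)
        ok <- i < j & prot[i] != prot[j]
        picked <- unique(rbind(picked, cbind(i[ok], j[ok])))
      }
      picked[seq_len(maxPairs), , drop = FALSE]
    })
  } else {
    cmb <- t(utils::combn(seq_len(n), 2))
    diff_idx <- cmb[prot[cmb[, 1]] != prot[cmb[, 2]], , drop = FALSE]
  }
  same_idx <- cbind(match(same[, 1], rownames(m)),
                    match(same[, 2], rownames(m)))

  pairR <- function(idx, category) {
    r <- vapply(seq_len(nrow(idx)), function(k) {
      a <- m[idx[k, 1], ]; b <- m[idx[k, 2], ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < max(3, minOverlap)) return(NA_real_)
      suppressWarnings(stats::cor(a[ok], b[ok]))
    }, numeric(1))
    data.frame(feature1 = rownames(m)[idx[, 1]],
               feature2 = rownames(m)[idx[, 2]],
               category = category, r = r, stringsAsFactors = FALSE)
  }
  pairs <- rbind(pairR(same_idx, "same_protein"),
                 pairR(diff_idx, "different_protein"))
  excluded <- sum(is.na(pairs$r))
  pairs <- pairs[!is.na(pairs$r), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, summary = .catSummary(pairs),
                 nExcluded = excluded, minOverlap = minOverlap),
            class = "CorrelationSummary")
}

#' Coefficient of variation of replicates by abundance
#'
#' For every feature, the CV (`sd/mean`, denominator `n - 1`) of the
#' UNLOGGED intensities within each replicate group with at least two
#' observed injections, averaged across groups. CV is only meaningful on the
#' raw ratio scale, hence the unlogging. Features are binned by their mean
#' log10 raw abundance; precision is abundance-dependent, so per-bin
#' summaries are reported. Successful adjustment lowers replicate CVs.
#'
#' @param x a [BatchExperiment-class] with a replicate-group column.
#' @param nBins number of equal-width abundance bins.
#' @return list with `features` (`feature_id`, `mean_log10_abundance`,
#'   `cv`, `n_groups`, `bin`) and `bins` (per-bin count, mean and median
#'   CV).
#' @export
cvByAbundance <- function(x, nBins = 10) {
  reps <- replicateGroups(x)
  if (is.null(reps)) stop("no replicate-group column declared")
  m <- intensityMatrix(x)
  grp <- split(seq_len(ncol(m)), reps)
  grp <- grp[vapply(grp, length, integer(1)) >= 2]
  if (!length(grp)) stop("no replicate group with >= 2 samples")
  raw <- 2^m
  rows <- lapply(seq_len(nrow(m)), function(g) {
    cvs <- vapply(grp, function(idx) {
      v <- raw[g, idx]
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      stats::sd(v) / mean(v)
    }, numeric(1))
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) return(NULL)
    ab <- mean(raw[g, ], na.rm = TRUE)
    data.frame(feature_id = rownames(m)[g],
               mean_log10_abundance = log10(ab),
               cv = mean(cvs), n_groups = length(cvs),
               stringsAsFactors = FALSE)
  })
  feats <- do.call(rbind, rows)
  if (is.null(feats)) stop("no feature with replicated observations")
  brk <- seq(min(feats$mean_log10_abundance),
             max(feats$mean_log10_abundance), length.out = nBins + 1)
  brk[1] <- brk[1] - 1e-9
  feats$bin <- cut(feats$mean_log10_abundance, brk, labels = FALSE)
  bins <- do.call(rbind, lapply(sort(unique(feats$bin)), function(b) {
    v <- feats$cv[feats$bin == b]
    data.frame(bin = b, n = length(v), mean_cv = mean(v),
               median_cv = stats::median(v), stringsAsFactors = FALSE)
  }))
  list(features = feats, bins = bins)
}

#' Before/after quality-control comparison
#'
#' Runs the proximity-based controls (sample correlations, peptide
#' correlations, replicate CVs, PVCA) on a raw and an adjusted table over
#' the same feature/sample universe and reports paired summaries plus
#' deltas. Negative controls: batch-linked quantities (within-vs-between
#' correlation gap, PVCA batch proportions) should shrink. Positive
#' controls: replicate and same-protein correlations should hold or improve
#' and replicate CVs should drop.
#'
#' @param before,after two [BatchExperiment-class] objects with identical
#'   features, samples and annotation.
#' @param batchFactor declared batch factor for the correlation split and
#'   PVCA.
#' @param pvcaFactors factors for PVCA (default: the batch factor plus all
#'   declared biological factors).
#' @param minOverlap,maxPairs,seed passed to the correlation summaries.
#' @return list of class `"QcComparison"` with elements `before`, `after`
#'   (each holding the four reports) and `delta`.
#' @export
qcCompare <- function(before, after, batchFactor, pvcaFactors = NULL,
                      minOverlap = 50, maxPairs = 5000, seed = NULL) {
  stopifnot(is(before, "BatchExperiment"), is(after, "BatchExperiment"))
  if (!identical(dimnames(before), dimnames(after)))
    stop("feature/sample universe mismatch between 'before' and 'after'")
  if (!identical(runOrder(before), runOrder(after)))
    stop("annotation mismatch between 'before' and 'after'")
  if (is.null(pvcaFactors))
    pvcaFactors <- c(batchFactor, bioFactorNames(before))

  evalSide <- function(be) {
    list(
      sample_correlation = sampleCorrelationSummary(be, batchFactor,
                                                    minOverlap = minOverlap),
      peptide_correlation = if (!is.null(proteinIds(be)))
        peptideCorrelationSummary(be, maxPairs = maxPairs, seed = seed)
        else NULL,
      cv = if (!is.null(replicateGroups(be))) cvByAbundance(be) else NULL,
      pvca = pvca(be, pvcaFactors)
    )
  }
  b <- evalSide(before)
  a <- evalSide(after)

  medByCat <- function(cs) {
    v <- cs$summary$median
    names(v) <- cs$summary$category
    v
  }
  meanByCat <- function(cs) {
    v <- cs$summary$mean
    names(v) <- cs$summary$category
    v
  }
  deltaNamed <- function(va, vb) {
    keys <- union(names(va), names(vb))
    out <- vapply(keys, function(k)
      (if (k %in% names(va)) va[[k]] else NA_real_) -
      (if (k %in% names(vb)) vb[[k]] else NA_real_), numeric(1))
    out
  }
  pvcaVec <- function(p) {
    v <- pvcaTable(p)$proportion
    names(v) <- pvcaTable(p)$source
    v
  }
  delta <- list(
    sample_correlation_median = deltaNamed(medByCat(a$sample_correlation),
                                           medByCat(b$sample_correlation)),
    peptide_correlation_mean = if (!is.null(a$peptide_correlation))
      deltaNamed(meanByCat(a$peptide_correlation),
                 meanByCat(b$peptide_correlation)) else NULL,
    cv_median = if (!is.null(a$cv))
      stats::median(a$cv$features$cv) - stats::median(b$cv$features$cv)
      else NULL,
    pvca = deltaNamed(pvcaVec(a$pvca), pvcaVec(b$pvca))
  )
  structure(list(before = b, after = a, delta = delta),
            class = "QcComparison")
}

#' @export
print.QcComparison <- function(x, ...) {
  cat("QcComparison\n  delta of per-category median sample correlation:\n")
  print(round(x$delta$sample_correlation_median, 4))
  cat("  delta of PVCA proportions:\n")
  print(round(x$delta$pvca, 4))
  if (!is.null(x$delta$cv_median))
    cat("  delta of median replicate CV:", round(x$delta$cv_median, 5), "\n")
  invisible(x)
}
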