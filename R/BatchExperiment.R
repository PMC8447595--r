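#' Construct a BatchExperiment
#'
#' Assemble the package's central container from a log2 intensity matrix and
#' a sample annotation table. Samples are matched between the matrix columns
#' and the annotation by sample identifier; the annotation may be a superset
#' of the measured samples but every measured sample must be annotated.
#'
#' @param intensity numeric matrix of log2 intensities, features in rows
#'   (rownames = feature ids), samples in columns (colnames = sample ids);
#'   `NA` marks a missing measurement.
#' @param sampleAnnotation `data.frame` with a `sample_id` column, an integer
#'   `run_order` column (unique rank of MS acquisition; resolve timestamp ties
#'   before import), and one column per technical/biological factor.
#' @param batchFactors character, names of the annotation columns that are
#'   technical batch factors (e.g. `"MS_batch"`, `"digestion_batch"`).
#' @param bioFactors character, names of biological factor columns.
#' @param replicateGroup optional name of the column whose shared values mark
#'   replicate injections of the same specimen, or `NULL`.
#' @param featureAnnotation optional `data.frame` with columns `feature_id`,
#'   `protein_id` and (optionally) logical `is_spike_in`; every feature of the
#'   matrix used by protein-level QC must appear exactly once.
#' @return a validated [BatchExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' ann <- data.frame(sample_id = paste0("s", 1:4), run_order = 1:4,
#'                   MS_batch = c("B1", "B1", "B2", "B2"))
#' be <- BatchExperiment(m, ann, batchFactors = "MS_batch")
#' @export
BatchExperiment <- function(intensity, sampleAnnotation,
                            batchFactors,
                            bioFactors = character(0),
                            replicateGroup = NULL,
                            featureAnnotation = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(colnames(intensity)))
    stop("intensity matrix must have sample ids as column names")
  if (is.null(rownames(intensity)))
    stop("intensity matrix must have feature ids as row names")
  sampleAnnotation <- as.data.frame(sampleAnnotation)
  if (!"sample_id" %in% names(sampleAnnotation))
    stop("sampleAnnotation must contain a 'sample_id' column")
  if (anyDuplicated(sampleAnnotation$sample_id))
    stop("sampleAnnotation sample_id values must be unique")
  missing_ann <- setdiff(colnames(intensity), sampleAnnotation$sample_id)
  if (length(missing_ann))
    stop("samples without annotation: ", paste(missing_ann, collapse = ", "))
  idx <- match(colnames(intensity), sampleAnnotation$sample_id)
  cd <- sampleAnnotation[idx, setdiff(names(sampleAnnotation), "sample_id"),
                         drop = FALSE]
  rownames(cd) <- colnames(intensity)
  if (!"run_order" %in% names(cd))
    stop("sampleAnnotation must contain a 'run_order' column")
  cd$run_order <- as.integer(cd$run_order)

  rd <- NULL
  if (!is.null(featureAnnotation)) {
    featureAnnotation <- as.data.frame(featureAnnotation)
    if (!all(c("feature_id", "protein_id") %in% names(featureAnnotation)))
      stop("featureAnnotation needs 'feature_id' and 'protein_id' columns")
    if (anyDuplicated(featureAnnotation$feature_id))
      stop("featureAnnotation feature_id values must be unique")
    fidx <- match(rownames(intensity), featureAnnotation$feature_id)
    rd <- featureAnnotation[fidx,
                            setdiff(names(featureAnnotation), "feature_id"),
                            drop = FALSE]
    if (!"is_spike_in" %in% names(rd)) rd$is_spike_in <- FALSE
    rd$is_spike_in[is.na(rd$is_spike_in)] <- FALSE
    rownames(rd) <- rownames(intensity)
  }

  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = DataFrame(cd),
    rowData = if (is.null(rd)) NULL else DataFrame(rd)
  )
  metadata(se) <- list(
    batch_factors = as.character(batchFactors),
    bio_factors = as.character(bioFactors),
    replicate_group = if (is.null(replicateGroup)) NA_character_ else
      replicateGroup,
    processing_log = list()
  )
  be <- as(se, "BatchExperiment")
  validObject(be)
  be
}

## ---- accessors --------------------------------------------------------

#' Accessors for BatchExperiment annotation roles
#'
#' @param x a [BatchExperiment-class].
#' @return `intensityMatrix`: the features x samples log2 matrix (`NA` =
#'   missing). `runOrder`: named integer vector of acquisition ranks.
#'   `batchFactorNames` / `bioFactorNames`: declared factor column names.
#'   `replicateGroupName`: the replicate column name or `NA`.
#'   `replicateGroups`: named vector of replicate labels (or `NULL`).
#'   `sampleFactor`: the per-sample levels of one annotation factor.
#'   `proteinIds` / `spikeInFeatures`: feature-level annotation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
intensityMatrix <- function(x) assay(x, "intensity")

#' @rdname accessors
#' @export
runOrder <- function(x) {
  ro <- colData(x)$run_order
  names(ro) <- colnames(x)
  ro
}

#' @rdname accessors
#' @export
batchFactorNames <- function(x) metadata(x)$batch_factors

#' @rdname accessors
#' @export
bioFactorNames <- function(x) metadata(x)$bio_factors

#' @rdname accessors
#' @export
replicateGroupName <- function(x) metadata(x)$replicate_group

#' @rdname accessors
#' @export
replicateGroups <- function(x) {
  rg <- replicateGroupName(x)
  if (is.null(rg) || is.na(rg)) return(NULL)
  v <- as.character(colData(x)[[rg]])
  names(v) <- colnames(x)
  v
}

#' @rdname accessors
#' @param factor name of a colData annotation column.
#' @export
sampleFactor <- function(x, factor) {
  if (!factor %in% colnames(colData(x)))
    stop("unknown annotation factor: ", factor)
  v <- as.character(colData(x)[[factor]])
  names(v) <- colnames(x)
  v
}

#' @rdname accessors
#' @export
proteinIds <- function(x) {
  rd <- rowData(x)
  if (!"protein_id" %in% colnames(rd)) return(NULL)
  v <- as.character(rd$protein_id)
  names(v) <- rownames(x)
  v
}

#' @rdname accessors
#' @export
spikeInFeatures <- function(x) {
  rd <- rowData(x)
  if (!"is_spike_in" %in% colnames(rd)) return(character(0))
  rownames(x)[which(rd$is_spike_in)]
}

#' @rdname accessors
#' @export
processingLog <- function(x) metadata(x)$processing_log

## internal: replace the intensity assay and append a provenance entry
.updateIntensities <- function(x, m, stage, params = list()) {
  stopifnot(identical(dim(m), dim(x)))
  assay(x, "intensity") <- m
  log <- metadata(x)$processing_log
  log[[length(log) + 1L]] <- c(list(stage = stage), params)
  metadata(x)$processing_log <- log
  validObject(x)
  x
}

## internal: check a batch factor name and return per-sample levels
.batchLevels <- function(x, batchFactor) {
  if (!batchFactor %in% batchFactorNames(x))
    stop("'", batchFactor, "' is not a declared batch factor (declared: ",
         paste(batchFactorNames(x), collapse = ", "), ")")
  sampleFactor(x, batchFactor)
}

setMethod("show", "BatchExperiment", function(object) {
  m <- intensityMatrix(object)
  cat(sprintf("BatchExperiment: %d features x %d samples (%.1f%% missing)\n",
              nrow(m), ncol(m), 100 * mean(is.na(m))))
  cat("  batch factors:", paste(batchFactorNames(object), collapse = ", "),
      "\n")
  if (length(bioFactorNames(object)))
    cat("  bio factors:  ", paste(bioFactorNames(object), collapse = ", "),
        "\n")
  rg <- replicateGroupName(object)
  if (!is.na(rg)) cat("  replicates:   column", rg, "\n")
  log <- processingLog(object)
  if (length(log))
    cat("  processing:   ",
        paste(vapply(log, `[[`, "", "stage"), collapse = " -> "), "\n")
})

setMethod("show", "CombatParams", function(object) {
  cat(sprintf(
    "CombatParams: %d features, %d batches; EB tolerance %.1e, %s iterations\n",
    nrow(object@gammaStar), ncol(object@gammaStar), object@tolerance,
    paste(object@iterations, collapse = "/")))
})

setMethod("show", "PvcaResult", function(object) {
  cat(sprintf("PvcaResult: %d PCs retained (cumulative variance >= %.2f)\n",
              object@nComponents, object@varianceThreshold))
  tab <- object@table[order(-object@table$proportion), ]
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-24s %6.3f\n", tab$source[i], tab$proportion[i]))
})

#' @rdname PvcaResult-class
#' @param x a `PvcaResult`.
#' @return `pvcaTable(x)` returns the `data.frame` of variance proportions.
#' @export
pvcaTable <- function(x) x@table
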