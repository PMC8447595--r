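#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   colData colData<- rowData rowData<-
NULL

#' BatchExperiment: an annotated log2 intensity matrix
#'
#' `BatchExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' is the central container of the package. It holds a single `"intensity"`
#' assay of log2-scale abundances (features x samples, `NA` = not observed),
#' per-sample annotation in `colData()` (a unique integer `run_order` plus one
#' column per declared technical batch factor, biological factor and the
#' optional replicate-group label), and optional per-feature annotation in
#' `rowData()` (`protein_id`, `is_spike_in`). Which annotation columns play
#' which role is recorded in `metadata()` and queried through
#' [batchFactorNames()], [bioFactorNames()] and [replicateGroupName()].
#'
#' Missing measurements are represented as `NA` cells, never as sentinel
#' zeros; every operation in the package preserves the missingness pattern
#' unless it is an explicit, mask-tracked imputation.
#'
#' @section Validity:
#' \itemize{
#'   \item assay `"intensity"` exists, is numeric, and every non-`NA` cell is
#'     finite;
#'   \item `run_order` is present, integer-valued, positive and unique across
#'     samples (batches need not be contiguous in running order);
#'   \item every declared batch factor column exists and has no missing level;
#'   \item feature and sample identifiers (dimnames) are unique and non-empty.
#' }
#'
#' @seealso [BatchExperiment()] for construction, [readBatchExperiment()] for
#'   construction from delimited files.
#' @export
setClass("BatchExperiment", contains = "SummarizedExperiment")

.be_required_metadata <- c("batch_factors", "bio_factors", "replicate_group")

setValidity("BatchExperiment", function(object) {
  msg <- character(0)
  if (!"intensity" %in% names(assays(object)))
    return("assay 'intensity' is required")
  m <- assay(object, "intensity")
  if (!is.numeric(m))
    msg <- c(msg, "assay 'intensity' must be numeric")
  if (any(is.infinite(m) | is.nan(m)))
    msg <- c(msg, "non-missing intensities must be finite")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature identifiers (rownames) must exist and be unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must exist and be unique")
  cd <- colData(object)
  if (!"run_order" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'run_order' column")
  } else {
    ro <- cd$run_order
    if (anyNA(ro) || any(ro != as.integer(ro)) || any(ro < 1))
      msg <- c(msg, "run_order must be positive integers")
    if (anyDuplicated(ro))
      msg <- c(msg, "run_order must be unique across samples")
  }
  md <- metadata(object)
  for (k in .be_required_metadata)
    if (!k %in% names(md))
      msg <- c(msg, sprintf("metadata entry '%s' is required", k))
  bf <- md$batch_factors
  for (f in c(bf, md$bio_factors)) {
    if (!f %in% colnames(cd)) {
      msg <- c(msg, sprintf("declared factor '%s' is not a colData column", f))
    } else if (f %in% bf && anyNA(cd[[f]])) {
      msg <- c(msg, sprintf("batch factor '%s' has missing levels", f))
    }
  }
  rg <- md$replicate_group
  if (!is.null(rg) && !is.na(rg) && !rg %in% colnames(cd))
    msg <- c(msg, sprintf("replicate group column '%s' not in colData", rg))
  if (length(msg)) msg else TRUE
})

#' Empirical-Bayes location-scale adjustment parameters
#'
#' Container for every parameter of the parametric empirical-Bayes
#' location-scale batch model fitted by [combatAdjust()]: the per-feature
#' grand mean and pooled variance used for standardisation, the raw
#' per-feature per-batch location (`gammaHat`) and scale (`deltaHat`)
#' estimates, the moment-matched hyperparameters of the normal prior on the
#' locations (`gammaBar`, `t2`) and the inverse-gamma prior on the scales
#' (`aPrior`, `bPrior`), the shrunk posterior estimates (`gammaStar`,
#' `deltaStar`), and the iteration counts / tolerance of the conditional
#' posterior updates.
#'
#' @slot grandMean numeric, per-feature standardisation mean (including any
#'   covariate contribution averaged over samples).
#' @slot pooledVar numeric, per-feature pooled variance.
#' @slot gammaHat,deltaHat feature x batch matrices of raw batch location and
#'   scale estimates on the standardised scale.
#' @slot gammaBar,t2,aPrior,bPrior per-batch empirical-Bayes hyperparameters.
#' @slot gammaStar,deltaStar feature x batch matrices of shrunk estimates.
#' @slot iterations integer, per-batch count of conditional-posterior sweeps.
#' @slot tolerance numeric, convergence tolerance on the relative parameter
#'   change.
#' @export
setClass("CombatParams",
  representation(
    grandMean = "numeric", pooledVar = "numeric",
    gammaHat = "matrix", deltaHat = "matrix",
    gammaBar = "numeric", t2 = "numeric",
    aPrior = "numeric", bPrior = "numeric",
    gammaStar = "matrix", deltaStar = "matrix",
    iterations = "integer", tolerance = "numeric"
  )
)

setValidity("CombatParams", function(object) {
  if (any(object@deltaStar <= 0, na.rm = TRUE))
    return("shrunk scale parameters must be positive")
  TRUE
})

#' Principal variance component analysis result
#'
#' Eigenvalue-weighted variance-component decomposition of the leading
#' principal components of an intensity matrix, attributing variance to
#' annotated factors (and, optionally, their pairwise interactions) plus a
#' residual.
#'
#' @slot table `data.frame` with columns `source` (factor name, `"A:B"`
#'   interaction, or `"residual"`) and `proportion` (weighted fraction in
#'   `[0, 1]`, summing to 1).
#' @slot nComponents integer, number of principal components retained.
#' @slot varianceThreshold numeric, the cumulative-variance cutoff used to
#'   choose `nComponents`.
#' @slot eigenFractions numeric, eigenvalue fraction of total variance for
#'   each retained component.
#' @slot nFeaturesUsed,nFeaturesDropped integer, complete features used and
#'   incomplete features discarded by the missingness policy.
#' @export
setClass("PvcaResult",
  representation(
    table = "data.frame", nComponents = "integer",
    varianceThreshold = "numeric", eigenFractions = "numeric",
    nFeaturesUsed = "integer", nFeaturesDropped = "integer"
  )
)

setValidity("PvcaResult", function(object) {
  tab <- object@table
  if (!all(c("source", "proportion") %in% names(tab)))
    return("table must have 'source' and 'proportion' columns")
  if (any(tab$proportion < -1e-12))
    return("proportions must be non-negative")
  if (abs(sum(tab$proportion) - 1) > 1e-8)
    return("proportions must sum to 1")
  if (!"residual" %in% tab$source)
    return("a 'residual' source is required")
  TRUE
})
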