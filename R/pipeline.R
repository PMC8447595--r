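## Config-driven workflow runner binding the five steps together.
##
## There is deliberately no single-click default: the config must name every
## method and parameter explicitly, and any step may be skipped — minimal
## data manipulation is a feature, not a limitation.

#' Run the batch-effect workflow from a YAML config
#'
#' Executes the requested steps of the workflow — initial assessment,
#' normalization, diagnostics, batch-effect correction, quality control —
#' in order on delimited-text inputs, writing per-step TSV outputs plus a
#' machine-readable JSON run log (methods, parameters, seeds,
#' dropped-feature counts, warnings) to the output directory.
#'
#' Config layout (YAML):
#' \preformatted{
#' input:
#'   intensities: long.tsv        # or wide.tsv with format: wide
#'   format: long
#'   sample_annotation: samples.tsv
#'   feature_annotation: features.tsv   # optional
#' factors:
#'   batch: [MS_batch]
#'   biological: [group]
#'   replicate: replicate_group         # optional
#' seed: 17
#' steps:                         # every requested step names its method
#'   assess: {stat: mean}
#'   normalize: {method: median}  # median | quantile | zscore
#'   diagnostics:
#'     pca: true
#'     hclust: {distance: euclidean, linkage: complete}
#'     pvca: {factors: [MS_batch, group], threshold: 0.6}
#'   correction:
#'     method: loess_median       # loess_median | loess_combat |
#'                                # median | combat
#'     batch_factor: MS_batch
#'     span: 0.75
#'   qc: {batch_factor: MS_batch, min_overlap: 50}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param outDir output directory (created if absent).
#' @return invisibly, a list with the final [BatchExperiment-class]
#'   objects per stage and the run log.
#' @export
runWorkflow <- function(config, outDir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              steps = list(), warnings = list())
  note <- function(step, ...) {
    log$steps[[step]] <<- list(...)
  }
  withCallingHandlers({
    roles <- list(batch = as.character(config$factors$batch),
                  biological = as.character(config$factors$biological %||%
                                            character(0)),
                  replicate = config$factors$replicate)
    be <- tryCatch(
      readBatchExperiment(
        intensityPath = config$input$intensities,
        sampleAnnotationPath = config$input$sample_annotation,
        roles = roles,
        featureAnnotationPath = config$input$feature_annotation,
        format = config$input$format %||% "long"
      ),
      error = function(e) stop("step 'input' failed: ", conditionMessage(e),
                               call. = FALSE))
    stages <- list(raw = be)
    steps <- config$steps %||% list()

    if (!is.null(steps$assess)) {
      s <- sampleOrderSummary(be, stat = steps$assess$stat %||% "mean")
      utils::write.table(s, file.path(outDir, "assess_sample_order.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("assess", stat = steps$assess$stat %||% "mean",
           output = "assess_sample_order.tsv")
    }

    current <- be
    if (!is.null(steps$normalize)) {
      method <- steps$normalize$method
      if (is.null(method))
        stop("step 'normalize' failed: a method must be named explicitly")
      current <- tryCatch(switch(method,
        median = normalizeMedian(current),
        quantile = normalizeQuantile(current),
        zscore = normalizeZscore(current),
        stop("unknown normalization method: ", method)),
        error = function(e) stop("step 'normalize' failed: ",
                                 conditionMessage(e), call. = FALSE))
      stages$normalized <- current
      writeLongTable(current, file.path(outDir, "normalized_long.tsv"))
      note("normalize", method = method, output = "normalized_long.tsv")
    }

    if (!is.null(steps$diagnostics)) {
      d <- steps$diagnostics
      if (isTRUE(d$pca)) {
        pc <- pcaScores(current)
        sc <- data.frame(sample_id = rownames(pc$scores), pc$scores,
                         check.names = FALSE)
        utils::write.table(sc, file.path(outDir, "diagnostics_pca.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("diagnostics_pca",
             variance_fraction = unname(pc$varianceFraction[1:min(5,
               length(pc$varianceFraction))]),
             n_features_dropped = pc$nFeaturesDropped)
      }
      if (!is.null(d$hclust)) {
        hc <- hierarchicalCluster(current,
                                  distance = d$hclust$distance %||%
                                    "euclidean",
                                  linkage = d$hclust$linkage %||% "complete")
        utils::write.table(hc$leafAnnotation,
                           file.path(outDir, "diagnostics_hclust_leaves.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("diagnostics_hclust", distance = hc$distance,
             linkage = hc$linkage)
      }
      if (!is.null(d$pvca)) {
        pv <- pvca(current, factors = d$pvca$factors,
                   varianceThreshold = d$pvca$threshold %||% 0.6)
        utils::write.table(pvcaTable(pv),
                           file.path(outDir, "diagnostics_pvca.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("diagnostics_pvca", factors = d$pvca$factors,
             n_components = pv@nComponents,
             n_features_dropped = pv@nFeaturesDropped)
      }
      if (!is.null(d$trend_features)) {
        tr <- featureTrend(current, featureIds = d$trend_features)
        utils::write.table(tr, file.path(outDir, "diagnostics_trends.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("diagnostics_trends", features = d$trend_features)
      }
    }

    if (!is.null(steps$correction)) {
      cstep <- steps$correction
      method <- cstep$method
      if (is.null(method))
        stop("step 'correction' failed: a method must be named explicitly")
      bf <- cstep$batch_factor
      res <- tryCatch(switch(method,
        loess_median = adjustTwoStep(current, bf,
                                     span = cstep$span %||% 0.75,
                                     discreteMethod = "median"),
        loess_combat = adjustTwoStep(current, bf,
                                     span = cstep$span %||% 0.75,
                                     discreteMethod = "combat",
                                     covariates = cstep$covariates),
        median = list(corrected = centerDiscrete(current, bf,
                                                 stat = "median"),
                      driftFits = NULL),
        combat = {
          cb <- combatAdjust(current, bf, covariates = cstep$covariates)
          list(corrected = cb$corrected, driftFits = NULL)
        },
        stop("unknown correction method: ", method)),
        error = function(e) stop("step 'correction' failed: ",
                                 conditionMessage(e), call. = FALSE))
      corrected <- res$corrected
      stages$corrected <- corrected
      writeLongTable(corrected, file.path(outDir, "corrected_long.tsv"))
      if (!is.null(res$driftFits) && nrow(res$driftFits))
        utils::write.table(res$driftFits,
                           file.path(outDir, "drift_fits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      note("correction", method = method, batch_factor = bf,
           span = cstep$span %||% 0.75,
           n_fallbacks = if (!is.null(res$fallbacks))
             nrow(res$fallbacks) else 0L,
           output = "corrected_long.tsv")
      current <- corrected
    }

    if (!is.null(steps$qc)) {
      q <- steps$qc
      ref <- stages$raw
      cmp <- tryCatch(
        qcCompare(ref, current, batchFactor = q$batch_factor,
                  minOverlap = q$min_overlap %||% 50,
                  seed = config$seed %||% 1L),
        error = function(e) stop("step 'qc' failed: ", conditionMessage(e),
                                 call. = FALSE))
      utils::write.table(cmp$after$sample_correlation$summary,
                         file.path(outDir, "qc_sample_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pvcaTable(cmp$after$pvca),
                         file.path(outDir, "qc_pvca.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("qc", batch_factor = q$batch_factor,
           delta_pvca = as.list(cmp$delta$pvca),
           delta_sample_correlation_median =
             as.list(cmp$delta$sample_correlation_median))
      stages$qc <- cmp
    }
    log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(stages = stages, log = log))
  }, warning = function(w) {
    log$warnings[[length(log$warnings) + 1L]] <<- conditionMessage(w)
    invokeRestart("muffleWarning")
  })
}
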