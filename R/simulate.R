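## Seeded generator of proteomics-like matrices with the structures the
## workflow diagnoses: per-batch signal drift over running order with
## feature-specific sensitivity, discrete per-feature batch shifts,
## protein-grouped peptides sharing biological effects, constant-amount
## spike-ins, replicate re-injections, and (optionally) batch- and
## abundance-coupled missingness. Every random component draws from its own
## named substream of the master seed, so adding one component never
## perturbs the others.

.subSeed <- function(seed, idx) {
  (as.integer(seed) %% 59999L) * 31013L + as.integer(idx)
}

## unit drift shapes on within-batch position p in [0, 1]; max |s| = 1,
## centered to mean 0 over the batch positions
.driftShape <- function(family, p) {
  s <- switch(family,
    linear = 1 - 2 * p,
    exponential_decay = {
      e <- exp(-2 * p)
      2 * (e - min(e)) / (max(e) - min(e)) - 1
    },
    sinusoid = sin(2 * pi * p),
    stop("unknown drift family: ", family)
  )
  s - mean(s)
}

#' Simulation specification
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' mid-sized discovery cohort: 100 proteins x 3 peptides plus 10 spike-ins,
#' 90 samples in 3 equal batches, exponential signal decay restarting at
#' each batch boundary (instrument cleaning) with amplitude 1 log2 unit and
#' per-feature sensitivity U(0.3, 1.5), per-feature discrete batch shifts
#' N(0, 0.5), a two-level biological group with per-protein effects
#' N(0, 0.5), measurement noise N(0, 0.3), 5 specimens injected twice as
#' replicates, and no missingness (switch it on explicitly for
#' missingness studies).
#'
#' @param nProteins number of proteins.
#' @param peptidesPerProtein peptides per protein (scalar, or vector of
#'   candidate counts sampled uniformly per protein).
#' @param nSamples number of injections (including replicate re-injections).
#' @param nBatches number of batches.
#' @param batchSizes optional integer vector summing to `nSamples`
#'   (default: as equal as possible, contiguous in run order).
#' @param driftFamily `"linear"`, `"exponential_decay"` or `"sinusoid"`
#'   (recycled over batches).
#' @param driftAmplitude maximum drift excursion from the batch mean, log2
#'   units (the drift curve spans about twice this).
#' @param shiftSd standard deviation of the per-feature per-batch discrete
#'   shifts, log2 units.
#' @param bioEffectSd standard deviation of the per-protein group effects,
#'   log2 units (sum-to-zero coded group contrasts); 0 disables the group
#'   signal.
#' @param individualSd standard deviation of per-specimen per-protein
#'   individual biological variation, log2 units; shared by all peptides of
#'   a protein and by replicate injections of the same specimen. This is
#'   what makes replicates more similar than unrelated same-group samples.
#' @param nBioGroups number of biological group levels.
#' @param noiseSd measurement noise standard deviation, log2 units.
#' @param nReplicateSpecimens specimens injected `replicateInjections`
#'   times each (re-injections are placed at random run positions, so
#'   replicate pairs span batches).
#' @param replicateInjections injections per replicated specimen.
#' @param spikeInCount constant-amount spike-in features (no biological
#'   effect, no discrete shift, full drift exposure).
#' @param missingRate base missingness probability (0 = complete data).
#' @param missingBatchOdds odds multiplier applied in the coupled batch
#'   (the last batch) — batch-coupled missingness.
#' @param missingAbundanceSlope logistic slope on (median - intensity):
#'   positive values make low-abundance cells more likely to be missing.
#' @param missingFeatureBatchRate probability that a (non-spike-in) feature
#'   is dropped entirely from the coupled batch — the feature-by-batch
#'   dropout pattern that breaks complete-matrix methods.
#' @param baselineMean,baselineSd protein baseline distribution, log2.
#' @param peptideJitterSd within-protein peptide baseline spread, log2.
#' @param sensitivityRange range of the uniform per-feature drift
#'   sensitivity.
#' @param seed master seed (mandatory; all substreams derive from it).
#' @return list of class `"SimulationSpec"`.
#' @export
simulationSpec <- function(nProteins = 100, peptidesPerProtein = 3,
                           nSamples = 90, nBatches = 3, batchSizes = NULL,
                           driftFamily = "exponential_decay",
                           driftAmplitude = 1.0, shiftSd = 0.5,
                           bioEffectSd = 0.5, nBioGroups = 2,
                           individualSd = 0.3, noiseSd = 0.3, nReplicateSpecimens = 5,
                           replicateInjections = 2, spikeInCount = 10,
                           missingRate = 0, missingBatchOdds = 1,
                           missingAbundanceSlope = 0,
                           missingFeatureBatchRate = 0,
                           baselineMean = 20, baselineSd = 2,
                           peptideJitterSd = 1,
                           sensitivityRange = c(0.3, 1.5), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(batchSizes)) {
    base <- nSamples %/% nBatches
    batchSizes <- rep(base, nBatches)
    extra <- nSamples - sum(batchSizes)
    if (extra > 0) batchSizes[seq_len(extra)] <- batchSizes[seq_len(extra)] + 1L
  }
  if (sum(batchSizes) != nSamples)
    stop("batchSizes must sum to nSamples")
  n_extra <- nReplicateSpecimens * (replicateInjections - 1)
  if (nReplicateSpecimens > 0 && replicateInjections < 2)
    stop("replicateInjections must be >= 2 when replicates are requested")
  if (n_extra >= nSamples)
    stop("replicate injections exceed the number of samples")
  structure(as.list(environment()), class = "SimulationSpec")
}

#' @export
print.SimulationSpec <- function(x, ...) {
  cat(sprintf(paste0(
    "SimulationSpec: %d proteins, %d samples, %d batches, drift %s (A=%g),",
    " shift sd %g, noise sd %g, seed %s\n"),
    x$nProteins, x$nSamples, x$nBatches, x$driftFamily, x$driftAmplitude,
    x$shiftSd, x$noiseSd, format(x$seed)))
  invisible(x)
}

#' Simulate a proteomics batch-effect dataset
#'
#' Generates `intensity = baseline + bioeffect + batch shift +
#' sensitivity * drift(run order) + noise` per feature and sample,
#' then applies the missingness model. Peptides of one protein share a
#' baseline (up to jitter) and the protein's biological effect; spike-ins
#' have no biological effect and no discrete shift but full drift exposure.
#' The returned ground truth stores every additive component, so recovery
#' tests can compare against the drift-free or shift-free signal exactly.
#'
#' @param spec a [simulationSpec()].
#' @return list with `experiment` (a [BatchExperiment-class]) and
#'   `groundTruth` (list of component matrices `bioeffect`, `shift`,
#'   `drift`, `noise`, vector `baseline`, matrix `complete` =
#'   pre-missingness intensities, `missingMask`, `driftCurve` per sample
#'   unit shape, `sensitivity`, `specimen`, and the `spec`).
#' @export
simulateExperiment <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  seed <- spec$seed

  ## features ------------------------------------------------------------
  ppp <- .withSeed(.subSeed(seed, 1L), {
    if (length(spec$peptidesPerProtein) == 1) {
      rep(spec$peptidesPerProtein, spec$nProteins)
    } else {
      sample(spec$peptidesPerProtein, spec$nProteins, replace = TRUE)
    }
  })
  protein_id <- c(rep(sprintf("prot_%03d", seq_len(spec$nProteins)), ppp),
                  sprintf("spike_%02d", seq_len(spec$spikeInCount)))
  feature_id <- c(unlist(lapply(seq_len(spec$nProteins), function(p)
    sprintf("pep_%03d_%d", p, seq_len(ppp[p])))),
    sprintf("spikepep_%02d", seq_len(spec$spikeInCount)))
  is_spike <- c(rep(FALSE, sum(ppp)), rep(TRUE, spec$spikeInCount))
  G <- length(feature_id)

  ## samples, batches, replicates ----------------------------------------
  n <- spec$nSamples
  batch_of <- rep(seq_len(spec$nBatches), times = spec$batchSizes)
  sample_id <- sprintf("s%03d", seq_len(n))
  n_extra <- spec$nReplicateSpecimens * (spec$replicateInjections - 1)
  n_specimens <- n - n_extra
  specimen <- .withSeed(.subSeed(seed, 2L), {
    spec_ids <- sprintf("spec_%03d", seq_len(n_specimens))
    rep_specs <- if (spec$nReplicateSpecimens > 0)
      sample(spec_ids, spec$nReplicateSpecimens) else character(0)
    pool <- c(spec_ids, rep(rep_specs, spec$replicateInjections - 1))
    sample(pool, n)  # random run positions for every injection
  })

  group_of_specimen <- .withSeed(.subSeed(seed, 3L), {
    g <- sample(rep_len(seq_len(spec$nBioGroups), n_specimens))
    names(g) <- sprintf("spec_%03d", seq_len(n_specimens))
    g
  })
  group <- group_of_specimen[specimen]

  ## component matrices ---------------------------------------------------
  baseline <- .withSeed(.subSeed(seed, 4L), {
    prot_base <- stats::rnorm(spec$nProteins, spec$baselineMean,
                              spec$baselineSd)
    pep_base <- rep(prot_base, ppp) +
      stats::rnorm(sum(ppp), 0, spec$peptideJitterSd)
    spike_base <- stats::rnorm(spec$spikeInCount, spec$baselineMean,
                               spec$baselineSd)
    c(pep_base, spike_base)
  })
  names(baseline) <- feature_id

  prot_effects <- .withSeed(.subSeed(seed, 5L), {
    e <- matrix(stats::rnorm(spec$nProteins * spec$nBioGroups, 0,
                             spec$bioEffectSd),
                spec$nProteins, spec$nBioGroups)
    e - rowMeans(e)  # sum-to-zero coding: effects are group contrasts
  })
  feat_effects <- rbind(prot_effects[rep(seq_len(spec$nProteins), ppp), ,
                                     drop = FALSE],
                        matrix(0, spec$spikeInCount, spec$nBioGroups))
  bioeffect <- feat_effects[, group, drop = FALSE]
  ## individual biological variation: per specimen per protein, shared by
  ## the protein's peptides and by replicate injections of the specimen
  indiv_prot <- .withSeed(.subSeed(seed, 10L),
    matrix(stats::rnorm(spec$nProteins * n_specimens, 0, spec$individualSd),
           spec$nProteins, n_specimens,
           dimnames = list(NULL, sprintf("spec_%03d", seq_len(n_specimens)))))
  indiv <- rbind(indiv_prot[rep(seq_len(spec$nProteins), ppp), specimen,
                            drop = FALSE],
                 matrix(0, spec$spikeInCount, n))
  bioeffect <- bioeffect + indiv
  dimnames(bioeffect) <- list(feature_id, sample_id)

  shift_fb <- .withSeed(.subSeed(seed, 6L), {
    s <- matrix(stats::rnorm(G * spec$nBatches, 0, spec$shiftSd),
                G, spec$nBatches)
    s[is_spike, ] <- 0
    s
  })
  shift <- shift_fb[, batch_of, drop = FALSE]
  dimnames(shift) <- list(feature_id, sample_id)

  fam <- rep_len(spec$driftFamily, spec$nBatches)
  drift_curve <- numeric(n)
  for (b in seq_len(spec$nBatches)) {
    idx <- which(batch_of == b)
    k <- length(idx)
    p <- if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1)
    drift_curve[idx] <- .driftShape(fam[b], p)
  }
  sensitivity <- .withSeed(.subSeed(seed, 7L),
    stats::runif(G, spec$sensitivityRange[1], spec$sensitivityRange[2]))
  drift <- outer(sensitivity, spec$driftAmplitude * drift_curve)
  dimnames(drift) <- list(feature_id, sample_id)

  noise <- .withSeed(.subSeed(seed, 8L),
    matrix(stats::rnorm(G * n, 0, spec$noiseSd), G, n,
           dimnames = list(feature_id, sample_id)))

  complete <- baseline + bioeffect + shift + drift + noise

  ## missingness ----------------------------------------------------------
  mask <- matrix(FALSE, G, n, dimnames = list(feature_id, sample_id))
  if (spec$missingRate > 0) {
    coupled <- batch_of == spec$nBatches
    med <- stats::median(complete)
    lp <- stats::qlogis(spec$missingRate) +
      log(spec$missingBatchOdds) * matrix(rep(coupled, each = G), G, n) +
      spec$missingAbundanceSlope * (med - complete)
    u <- .withSeed(.subSeed(seed, 9L), matrix(stats::runif(G * n), G, n))
    mask <- u < stats::plogis(lp)
  }
  if (spec$missingFeatureBatchRate > 0) {
    dropped <- .withSeed(.subSeed(seed, 11L),
      !is_spike & stats::runif(G) < spec$missingFeatureBatchRate)
    mask[dropped, batch_of == spec$nBatches] <- TRUE
  }
  intensity <- complete
  intensity[mask] <- NA_real_

  ann <- data.frame(
    sample_id = sample_id,
    run_order = seq_len(n),
    MS_batch = sprintf("B%d", batch_of),
    group = sprintf("g%d", group),
    specimen = specimen,
    stringsAsFactors = FALSE
  )
  inj_per_spec <- table(specimen)
  ann$replicate_group <- ifelse(inj_per_spec[specimen] > 1, specimen,
                                NA_character_)
  fann <- data.frame(feature_id = feature_id, protein_id = protein_id,
                     is_spike_in = is_spike, stringsAsFactors = FALSE)

  be <- BatchExperiment(intensity, ann, batchFactors = "MS_batch",
                        bioFactors = "group",
                        replicateGroup = "replicate_group",
                        featureAnnotation = fann)
  list(
    experiment = be,
    groundTruth = list(
      baseline = baseline, bioeffect = bioeffect, shift = shift,
      drift = drift, noise = noise, complete = complete,
      missingMask = mask, driftCurve = drift_curve,
      sensitivity = stats::setNames(sensitivity, feature_id),
      specimen = stats::setNames(specimen, sample_id), spec = spec
    )
  )
}

#' Worked example dataset
#'
#' Loads the tiny bundled dataset (6 proteins x 2 peptides, 12 samples in 2
#' batches, 2 replicate pairs, complete measurements, values rounded for
#' hand checking) from the package's `extdata` files through the standard
#' readers.
#'
#' @return a [BatchExperiment-class].
#' @export
workedFixture <- function() {
  p <- function(f) system.file("extdata", f, package = "ProteoBatchQC",
                               mustWork = TRUE)
  readBatchExperiment(
    intensityPath = p("fixture_intensities.tsv"),
    sampleAnnotationPath = p("fixture_samples.tsv"),
    roles = p("fixture_roles.yaml"),
    featureAnnotationPath = p("fixture_features.tsv"),
    format = "long"
  )
}
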