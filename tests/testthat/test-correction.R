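# makes a 2-batch experiment with a per-feature linear drift and optional
# discrete shift for recovery tests
driftBE <- function(n = 60, slope = 0.02, shift = 0, noise_sd = 0,
                    n_features = 5, seed = 17) {
  set.seed(seed)
  batch <- rep(c("A", "B"), each = n / 2)
  drift <- slope * (seq_len(n) - 1)
  m <- t(vapply(seq_len(n_features), function(g)
    20 + g + drift + shift * (batch == "B") + rnorm(n, 0, noise_sd),
    numeric(n)))
  rownames(m) <- sprintf("f%03d", seq_len(n_features))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  makeBE(m, batch)
}

test_that("drift correction is anchored at the feature-by-batch median", {
  # constant feature: loess reproduces the constant, correction is identity
  be <- driftBE(slope = 0, noise_sd = 0)
  res <- suppressWarnings(correctDrift(be, "batch", span = 0.7))
  expect_equal(intensityMatrix(res$corrected), intensityMatrix(be),
               tolerance = 1e-10)

  # constant + noise: the per-batch median moves by far less than the noise
  be2 <- driftBE(slope = 0, noise_sd = 0.2)
  res2 <- suppressWarnings(correctDrift(be2, "batch", span = 0.7))
  m0 <- intensityMatrix(be2)
  m1 <- intensityMatrix(res2$corrected)
  batch <- sampleFactor(be2, "batch")
  for (b in c("A", "B")) {
    i <- which(batch == b)
    expect_lt(max(abs(apply(m1[, i], 1, median) -
                      apply(m0[, i], 1, median))), 0.1)
  }
})

test_that("injected linear drift is removed at least tenfold", {
  # single 60-run batch: with several batches the median re-anchoring
  # deliberately keeps the discrete offsets for the second step
  set.seed(23)
  drift <- 0.02 * (0:59)
  m <- t(vapply(1:5, function(g) 20 + g + drift + rnorm(60, 0, 0.1),
                numeric(60)))
  rownames(m) <- sprintf("f%03d", 1:5)
  be <- makeBE(m, rep("A", 60))
  res <- suppressWarnings(correctDrift(be, "batch", span = 0.7))
  m1 <- intensityMatrix(res$corrected)
  ro <- as.numeric(runOrder(be))
  for (g in rownames(m1)) {
    fit <- coef(lm(m1[g, ] ~ ro))[2]
    expect_lt(abs(fit), 0.002)
  }
})

test_that("sparse feature-by-batch cells fall back to no correction", {
  be <- driftBE(n = 40, slope = 0.05, noise_sd = 0)
  m <- intensityMatrix(be)
  m["f001", 1:17] <- NA  # 3 observed values left in batch A
  be2 <- makeBE(m, sampleFactor(be, "batch"))
  res <- suppressWarnings(correctDrift(be2, "batch", minPoints = 8))
  expect_equal(nrow(res$fallbacks), 1)
  expect_equal(res$fallbacks$feature_id, "f001")
  expect_equal(res$fallbacks$n_points, 3)
  # untouched in the fallback batch
  expect_equal(intensityMatrix(res$corrected)["f001", 18:20],
               m["f001", 18:20])
  # fits are only reported at observed run orders
  expect_false(any(res$fits$feature_id == "f001" & res$fits$batch == "A"))
})

test_that("small batches trigger the overcorrection warning", {
  be <- driftBE(n = 30)
  w <- capture_warnings(correctDrift(be, "batch"))
  expect_true(any(grepl("fewer than 25 samples", w)))
  big <- suppressWarnings(simulateExperiment(simulationSpec(
    nProteins = 5, peptidesPerProtein = 1, nSamples = 60, nBatches = 2,
    nReplicateSpecimens = 0, spikeInCount = 0, seed = 1)))$experiment
  # 30-sample batches: only the not-normalized warning remains
  w <- capture_warnings(correctDrift(big, "MS_batch"))
  expect_false(any(grepl("fewer than 25", w)))
  expect_true(any(grepl("normaliz", w)))
})

test_that("discrete centering equalizes per-batch statistics exactly", {
  m <- matrix(c(5, 6, 7, 8, 9, 10), 1, 6,
              dimnames = list("f1", sprintf("s%d", 1:6)))
  be <- makeBE(m, rep(c("b1", "b2"), each = 3))
  out <- intensityMatrix(centerDiscrete(be, "batch", stat = "median"))
  expect_equal(unname(out[1, ]), c(6.5, 7.5, 8.5, 6.5, 7.5, 8.5))

  # single batch: identity
  be1 <- makeBE(m, rep("b1", 6))
  expect_equal(intensityMatrix(centerDiscrete(be1, "batch")), m)

  # sweep: 100 seeded features, per-feature per-batch medians all equal the
  # feature's global median; idempotent; missingness preserved
  mm <- randomMatrix(100, 30, 11, missing = 0.1)
  mm[1, ] <- 20  # keep all batches populated for every sample
  be2 <- makeBE(mm, rep(c("A", "B", "C"), each = 10))
  cd <- centerDiscrete(be2, "batch")
  m2 <- intensityMatrix(cd)
  expect_identical(is.na(m2), is.na(mm))
  batch <- sampleFactor(be2, "batch")
  for (b in unique(batch)) {
    i <- which(batch == b)
    sub <- m2[, i, drop = FALSE]
    has <- rowSums(!is.na(sub)) > 0
    expect_true(all(abs(apply(sub[has, ], 1, median, na.rm = TRUE) -
                        apply(m2[has, ], 1, median, na.rm = TRUE)) < 1e-12))
  }
  expect_equal(intensityMatrix(centerDiscrete(cd, "batch")), m2,
               tolerance = 1e-12)

  # mean variant
  cdm <- centerDiscrete(be2, "batch", stat = "mean")
  m3 <- intensityMatrix(cdm)
  for (b in unique(batch)) {
    i <- which(batch == b)
    sub <- m3[, i, drop = FALSE]
    has <- rowSums(!is.na(sub)) > 0
    expect_true(all(abs(rowMeans(sub[has, ], na.rm = TRUE) -
                        rowMeans(m3[has, ], na.rm = TRUE)) < 1e-12))
  }
})

test_that("exact linear drift plus centering restores flat features", {
  # no noise, per-batch linear drift, discrete shift: after the two steps
  # every feature is constant at its global median
  be <- driftBE(n = 60, slope = 0.02, shift = 1.5, noise_sd = 0)
  res <- suppressWarnings(adjustTwoStep(be, "batch", span = 0.7,
                                        discreteMethod = "median"))
  m1 <- intensityMatrix(res$corrected)
  glob <- apply(intensityMatrix(be), 1, median)
  batch <- sampleFactor(be, "batch")
  for (b in unique(batch)) {
    i <- which(batch == b)
    expect_true(all(abs(apply(m1[, i], 1, median) -
                        apply(m1, 1, median)) < 1e-8))
  }
  # flat to 1e-8 per sample
  expect_lt(max(abs(m1 - rowMeans(m1))), 1e-6)
})

test_that("two-step correction degenerates correctly at its limits", {
  # discrete shift only, no drift, no noise: identical to centering alone
  sim <- simulateExperiment(simulationSpec(
    nProteins = 20, peptidesPerProtein = 1, nSamples = 60, nBatches = 2,
    driftAmplitude = 0, noiseSd = 0, individualSd = 0, bioEffectSd = 0,
    nReplicateSpecimens = 0, spikeInCount = 0, seed = 3))
  be <- sim$experiment
  two <- suppressWarnings(adjustTwoStep(be, "MS_batch", span = 0.7))
  one <- centerDiscrete(be, "MS_batch")
  expect_equal(intensityMatrix(two$corrected), intensityMatrix(one),
               tolerance = 1e-6)

  # drift only, no shift: the discrete step is a near-no-op
  sim2 <- simulateExperiment(simulationSpec(
    nProteins = 20, peptidesPerProtein = 1, nSamples = 60, nBatches = 2,
    driftAmplitude = 1, shiftSd = 0, noiseSd = 0, individualSd = 0,
    bioEffectSd = 0, nReplicateSpecimens = 0, spikeInCount = 0, seed = 4))
  d1 <- suppressWarnings(correctDrift(sim2$experiment, "MS_batch",
                                      span = 0.7))
  d2 <- centerDiscrete(d1$corrected, "MS_batch")
  expect_lt(max(abs(intensityMatrix(d2) - intensityMatrix(d1$corrected))),
            0.05)

  # empty feature set passes through
  empty <- be[0, ]
  res <- suppressWarnings(adjustTwoStep(empty, "MS_batch"))
  expect_equal(nrow(res$corrected), 0)
})

test_that("correction never alters the missingness pattern", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 30, peptidesPerProtein = 1, nSamples = 60, nBatches = 2,
    missingRate = 0.1, nReplicateSpecimens = 0, spikeInCount = 0, seed = 9))
  be <- sim$experiment
  na0 <- is.na(intensityMatrix(be))
  res <- suppressWarnings(adjustTwoStep(be, "MS_batch", span = 0.7))
  expect_identical(is.na(intensityMatrix(res$corrected)), na0)
})
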