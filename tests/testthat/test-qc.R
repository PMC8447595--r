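test_that("sample correlations are classified and counted correctly", {
  # duplicated sample pair: r = 1, category replicate
  m <- randomMatrix(60, 4, 1)
  m[, 4] <- m[, 1]
  be <- makeBE(m, c("A", "A", "B", "B"),
               replicate = c("r1", NA, NA, "r1"))
  cs <- sampleCorrelationSummary(be, "batch", minOverlap = 10)
  dup <- cs$pairs[cs$pairs$sample1 == "s01" & cs$pairs$sample2 == "s04", ]
  expect_equal(dup$r, 1.0)
  expect_equal(dup$category, "replicate")

  # categories partition all retained pairs; counts sum to C(n,2) - excluded
  n <- ncol(be)
  expect_equal(nrow(cs$pairs) + cs$nExcluded, n * (n - 1) / 2)
  expect_equal(sum(cs$summary$n), nrow(cs$pairs))

  # pairs below the overlap threshold are excluded and counted
  m2 <- randomMatrix(60, 3, 2)
  m2[1:55, 3] <- NA
  be2 <- makeBE(m2, c("A", "A", "B"))
  cs2 <- sampleCorrelationSummary(be2, "batch", minOverlap = 50)
  expect_equal(cs2$nExcluded, 2)
  expect_equal(nrow(cs2$pairs), 1)
})

test_that("batch shifts open a within/between gap that centering closes", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 60, peptidesPerProtein = 1, nSamples = 60, nBatches = 3,
    driftAmplitude = 0, shiftSd = 0.6, seed = 19))
  be <- sim$experiment
  med <- function(x) {
    s <- sampleCorrelationSummary(x, "MS_batch")$summary
    v <- s$median
    names(v) <- s$category
    v
  }
  v0 <- med(be)
  expect_gt(v0["within_batch"], v0["between_batch"])
  v1 <- med(centerDiscrete(be, "MS_batch"))
  expect_lt(v1["within_batch"] - v1["between_batch"],
            v0["within_batch"] - v0["between_batch"])
})

test_that("peptide correlations separate same-protein from unrelated pairs", {
  # two identical peptide profiles: r = 1
  m <- randomMatrix(4, 30, 3)
  m[2, ] <- m[1, ]
  be <- makeBE(m, rep(c("A", "B"), each = 15),
               proteins = c("P1", "P1", "P2", "P3"))
  ps <- peptideCorrelationSummary(be)
  same <- ps$pairs[ps$pairs$category == "same_protein", ]
  expect_equal(nrow(same), 1)
  expect_equal(same$r, 1.0)

  # iid-noise peptides over 200 samples: unrelated means stay near zero
  m2 <- randomMatrix(40, 200, 4)
  be2 <- makeBE(m2, rep(c("A", "B"), each = 100),
                proteins = rep(sprintf("P%02d", 1:20), each = 2))
  ps2 <- peptideCorrelationSummary(be2, maxPairs = 500, seed = 7)
  diff_mean <- ps2$summary$mean[ps2$summary$category == "different_protein"]
  expect_lt(abs(diff_mean), 0.05)

  # subsampling without a seed is refused
  expect_error(peptideCorrelationSummary(be2, maxPairs = 10), "seed")
  # no multi-peptide protein is an error
  be3 <- makeBE(randomMatrix(3, 10, 5), rep("A", 10),
                proteins = c("P1", "P2", "P3"))
  expect_error(peptideCorrelationSummary(be3), "multi|>= 2")
})

test_that("correction shrinks unrelated-peptide correlations toward zero", {
  sim <- simulateExperiment(simulationSpec(seed = 6))
  be <- sim$experiment
  adj <- suppressWarnings(adjustTwoStep(normalizeMedian(be), "MS_batch",
                                        span = 0.7))$corrected
  pc <- function(x) {
    s <- peptideCorrelationSummary(x, maxPairs = 1500, seed = 2)$summary
    v <- s$mean
    names(v) <- s$category
    v
  }
  v0 <- pc(be)
  v1 <- pc(adj)
  expect_lt(abs(v1["different_protein"]), abs(v0["different_protein"]))
  expect_gt(v1["same_protein"], v1["different_protein"])
})

test_that("replicate CVs are computed on the raw scale and drop after centering", {
  # hand-checkable CVs
  m <- log2(matrix(c(100, 100, 100, 90, 110, 100), 2, 3, byrow = TRUE))
  rownames(m) <- c("f1", "f2")
  be <- makeBE(m, rep("A", 3), replicate = rep("r1", 3))
  cv <- cvByAbundance(be, nBins = 1)
  expect_equal(cv$features$cv[cv$features$feature_id == "f1"], 0)
  expect_equal(cv$features$cv[cv$features$feature_id == "f2"],
               sd(c(90, 110, 100)) / 100, tolerance = 1e-12)
  expect_error(cvByAbundance(makeBE(m, rep("A", 3))), "replicate")

  # batch-shifted cross-batch replicates: centering reduces CV for >= 90%
  set.seed(41)
  G <- 100
  base <- rnorm(G, 20, 1)
  shift <- rnorm(G, 0, 0.6)
  mm <- sapply(1:20, function(j) base + (j > 10) * shift)
  mm <- mm + matrix(rnorm(G * 20, 0, 0.1), G, 20)
  rownames(mm) <- sprintf("f%03d", 1:G)
  colnames(mm) <- sprintf("s%02d", 1:20)
  reps <- rep(NA_character_, 20)
  reps[c(1, 11)] <- "r1"; reps[c(2, 12)] <- "r2"; reps[c(3, 13)] <- "r3"
  be2 <- makeBE(mm, rep(c("A", "B"), each = 10), replicate = reps)
  cv0 <- cvByAbundance(be2)
  cv1 <- cvByAbundance(centerDiscrete(be2, "batch"))
  expect_gte(mean(cv1$features$cv <= cv0$features$cv + 1e-12), 0.9)
})

test_that("qcCompare pairs the controls and reacts to adjustment", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 40, nSamples = 45, nBatches = 3, seed = 8))
  be <- sim$experiment
  same <- qcCompare(be, be, "MS_batch", seed = 3)
  expect_true(all(abs(same$delta$sample_correlation_median) < 1e-12))
  expect_true(all(abs(same$delta$pvca) < 1e-12))
  expect_equal(same$delta$cv_median, 0)

  # universe mismatch is an integrity error
  expect_error(qcCompare(be, be[-1, ], "MS_batch"), "universe")
  perm <- be
  colnames(perm) <- rev(colnames(be))
  expect_error(qcCompare(be, perm, "MS_batch"), "universe|mismatch")

  # swapping before/after negates the deltas
  adj <- suppressWarnings(adjustTwoStep(be, "MS_batch",
                                        span = 0.7))$corrected
  ab <- qcCompare(be, adj, "MS_batch", seed = 3)
  ba <- qcCompare(adj, be, "MS_batch", seed = 3)
  expect_equal(ab$delta$pvca, -ba$delta$pvca, tolerance = 1e-10)
  expect_equal(ab$delta$sample_correlation_median,
               -ba$delta$sample_correlation_median, tolerance = 1e-10)
})

test_that("qcCompare shows the negative control shrinking after centering", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 40, nSamples = 45, nBatches = 3, driftAmplitude = 0,
    shiftSd = 0.8, seed = 8))
  be <- sim$experiment
  cmp <- qcCompare(be, centerDiscrete(be, "MS_batch"), "MS_batch",
                   seed = 3)
  # batch-linked metrics shrink ...
  expect_lt(cmp$delta$pvca[["MS_batch"]], 0)
  gap <- function(side) {
    s <- side$sample_correlation$summary
    s$median[s$category == "within_batch"] -
      s$median[s$category == "between_batch"]
  }
  expect_lt(gap(cmp$after), gap(cmp$before))
  # ... while the positive controls hold or improve
  repmed <- function(side) {
    s <- side$sample_correlation$summary
    s$median[s$category == "replicate"]
  }
  expect_gte(repmed(cmp$after), repmed(cmp$before) - 0.01)
  expect_lte(cmp$delta$cv_median, 1e-12)
})
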