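test_that("sample order summary reports quartiles and Tukey outliers", {
  m <- matrix(c(1, 2, 3, 100), 4, 1, dimnames = list(paste0("f", 1:4), "sA"))
  be <- makeBE(cbind(m, sB = c(5, 5, 5, 5)), c("b1", "b1"))
  s <- sampleOrderSummary(be, stat = "median")
  rowA <- s[s$sample_id == "sA", ]
  oq <- bruteQuartiles(c(1, 2, 3, 100))
  expect_equal(rowA$q1, unname(oq["q1"]))      # 1.75
  expect_equal(rowA$q3, unname(oq["q3"]))      # 27.25
  expect_equal(rowA$median, 2.5)
  expect_equal(rowA$n_outliers,
               unname(bruteOutlierCount(c(1, 2, 3, 100))))  # fence 65.5 -> 1
  rowB <- s[s$sample_id == "sB", ]
  expect_equal(rowB$q3 - rowB$q1, 0)
  expect_equal(rowB$n_outliers, 0)

  # ordering follows run_order even for unsorted sample ids
  m2 <- randomMatrix(5, 4, 1)
  colnames(m2) <- c("zeta", "alpha", "mu", "beta")
  be2 <- makeBE(m2, rep("b", 4), run_order = c(3, 1, 4, 2))
  s2 <- sampleOrderSummary(be2)
  expect_equal(s2$sample_id, c("alpha", "beta", "zeta", "mu"))
})

test_that("PCA scores reflect duplication, rank and cluster structure", {
  m <- randomMatrix(20, 5, 2)
  m <- cbind(m, dup = m[, 1])
  be <- makeBE(m, rep("b", 6))
  pc <- pcaScores(be)
  expect_equal(pc$scores[1, ], pc$scores[6, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$varianceFraction) <= 1e-12))
  expect_lte(sum(pc$varianceFraction), 1 + 1e-12)

  # rank-1 data: first component carries all variance
  u <- rnorm(10); v <- seq(1, 2, length.out = 6)
  r1 <- outer(u, v)
  rownames(r1) <- paste0("f", 1:10); colnames(r1) <- paste0("s", 1:6)
  pc1 <- pcaScores(makeBE(r1, rep("b", 6)))
  expect_equal(pc1$varianceFraction[1], 1.0, tolerance = 1e-10)

  # two shifted clusters separate on PC1 with no sign overlap
  set.seed(12)
  cl <- matrix(rnorm(50 * 20, 20, 0.5), 50, 20)
  cl[, 11:20] <- cl[, 11:20] + 2
  rownames(cl) <- paste0("f", 1:50); colnames(cl) <- paste0("s", 1:20)
  pc2 <- pcaScores(makeBE(cl, rep(c("A", "B"), each = 10)))
  signs <- sign(pc2$scores[, 1])
  expect_true(all(signs[1:10] == signs[1]) &&
              all(signs[11:20] == -signs[1]))

  # incomplete features are dropped and counted
  m3 <- randomMatrix(30, 6, 3)
  m3[1:7, 1] <- NA
  be3 <- makeBE(m3, rep("b", 6))
  expect_message(pc3 <- pcaScores(be3), "7 feature")
  expect_equal(pc3$nFeaturesDropped, 7)
  expect_error(pcaScores(be3, missingPolicy = "error"), "missing")
})

test_that("hierarchical clustering merges and heights are correct", {
  # d(A,B) < d(A,C) = d(B,C): first merge must be (A,B)
  m <- cbind(A = c(0, 0), B = c(1, 0), C = c(10, 10))
  rownames(m) <- c("f1", "f2")
  be <- makeBE(m, rep("b", 3))
  hc <- hierarchicalCluster(be, distance = "euclidean",
                            linkage = "average")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # leaves A and B
  expect_equal(length(hc$height), 2)            # n - 1 merges
  expect_setequal(hc$labels, c("A", "B", "C"))

  # duplicated samples merge at height zero
  m2 <- randomMatrix(10, 4, 5)
  m2[, 4] <- m2[, 1]
  hc2 <- hierarchicalCluster(makeBE(m2, rep("b", 4)))
  expect_equal(min(hc2$height), 0)

  # average-linkage heights match the O(n^3) brute-force agglomeration
  m3 <- randomMatrix(15, 6, 7)
  be3 <- makeBE(m3, rep(c("A", "B"), 3))
  hc3 <- hierarchicalCluster(be3, distance = "manhattan",
                             linkage = "average")
  d <- dist(t(m3), method = "manhattan")
  expect_equal(sort(hc3$height), sort(bruteAverageLinkageHeights(d)),
               tolerance = 1e-8)
  # monotone heights, annotation in leaf order
  expect_true(all(diff(hc3$height) >= -1e-12))
  expect_equal(hc3$leafAnnotation$sample_id, hc3$labels[hc3$order])
})

test_that("feature trends are extracted in run order without fill-in", {
  m <- randomMatrix(3, 5, 6)
  m[2, 3] <- NA
  be <- makeBE(m, rep("b", 5), run_order = c(5, 3, 1, 2, 4))
  tr <- featureTrend(be, "f001")
  expect_equal(nrow(tr), 5)
  expect_equal(tr$run_order, 1:5)
  tr2 <- featureTrend(be, "f002")
  expect_equal(nrow(tr2), 4)  # the missing cell is omitted
  expect_error(featureTrend(be, "nope"), "unknown feature")
})

test_that("spike-in features are selectable for trend diagnostics", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 10, nSamples = 30, nBatches = 2, spikeInCount = 4,
    nReplicateSpecimens = 0, seed = 2))
  tr <- featureTrend(sim$experiment, spikeInsOnly = TRUE)
  expect_setequal(unique(tr$feature_id),
                  spikeInFeatures(sim$experiment))
  expect_equal(length(spikeInFeatures(sim$experiment)), 4)
})

test_that("confounding is quantified by Cramer's V", {
  be <- makeBE(randomMatrix(5, 8, 8), rep(c("A", "B"), each = 4),
               group = rep(c("A", "B"), each = 4))
  rep_report <- confoundingReport(be, "batch", "group")
  expect_equal(rep_report$cramersV, 1.0)
  expect_true(rep_report$fullyConfounded)
  expect_equal(cramersV(matrix(c(10, 0, 0, 10), 2)), 1.0)

  set.seed(9)
  fx <- sample(c("a", "b"), 10000, replace = TRUE)
  fy <- sample(c("x", "y"), 10000, replace = TRUE)
  expect_lt(cramersV(table(fx, fy)), 0.05)
})

test_that("PVCA attributes batch-shift variance to the batch factor", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 40, peptidesPerProtein = 1, nSamples = 60, nBatches = 3,
    driftAmplitude = 0, shiftSd = 1.0, bioEffectSd = 0, individualSd = 0,
    noiseSd = 0.1, nReplicateSpecimens = 0, spikeInCount = 0, seed = 13))
  p <- pvca(sim$experiment, c("MS_batch", "group"))
  tab <- pvcaTable(p)
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-8)
  expect_gt(tab$proportion[tab$source == "MS_batch"], 0.8)
  expect_lt(tab$proportion[tab$source == "group"], 0.05)
  expect_true("residual" %in% tab$source)
})

test_that("PVCA is invariant to feature centering and sample relabeling", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 30, peptidesPerProtein = 1, nSamples = 40, nBatches = 2,
    nReplicateSpecimens = 0, spikeInCount = 0, seed = 14))
  be <- sim$experiment
  p0 <- pvcaTable(pvca(be, c("MS_batch", "group")))

  m <- intensityMatrix(be)
  centered <- m - rowMeans(m)
  beC <- makeBE(centered, sampleFactor(be, "MS_batch"),
                group = sampleFactor(be, "group"))
  pC <- pvcaTable(pvca(beC, c("batch", "group")))
  expect_equal(p0$proportion, pC$proportion, tolerance = 1e-4)

  # permute samples (labels travel with their annotation)
  set.seed(1)
  perm <- sample(ncol(be))
  beP <- be[, perm]
  pP <- pvcaTable(pvca(beP, c("MS_batch", "group")))
  expect_equal(p0$proportion, pP$proportion, tolerance = 1e-4)
})

test_that("PVCA rejects fully confounded factor pairs", {
  be <- makeBE(randomMatrix(10, 8, 1), rep(c("A", "B"), each = 4),
               group = rep(c("g1", "g2"), each = 4))
  expect_error(pvca(be, c("batch", "group")), "fully confounded")
})
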