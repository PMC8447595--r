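library(sva)

test_that("EB adjustment matches the reference parametric implementation", {
  set.seed(11)
  G <- 20; n <- 12
  batch <- rep(c("A", "B"), each = 6)
  m <- matrix(rnorm(G * n, 20, 1), G, n,
              dimnames = list(paste0("f", 1:G), paste0("s", 1:n)))
  m[, batch == "B"] <- m[, batch == "B"] + 1  # pure +1 location shift

  res <- combatFit(m, batch)
  ref <- suppressMessages(ComBat(m, batch = factor(batch),
                                 par.prior = TRUE, prior.plots = FALSE))
  expect_lt(max(abs(res$adjusted - ref)), 1e-6)

  # with a categorical covariate protecting the biological groups
  cov <- data.frame(g = factor(rep(c("x", "y"), 6)))
  res2 <- combatFit(m, batch, covariateData = cov)
  ref2 <- suppressMessages(ComBat(m, batch = factor(batch),
                                  mod = model.matrix(~g, cov),
                                  par.prior = TRUE, prior.plots = FALSE))
  expect_lt(max(abs(res2$adjusted - ref2)), 1e-6)

  # params expose the full location-scale model
  p <- res$params
  expect_s4_class(p, "CombatParams")
  expect_equal(dim(p@gammaStar), c(G, 2))
  expect_true(all(p@deltaStar > 0))
})

test_that("completeness and batch-size preconditions are enforced", {
  m <- randomMatrix(10, 8, 2)
  batch <- rep(c("A", "B"), each = 4)
  m["f003", batch == "B"] <- NA  # absent from batch B entirely
  expect_error(combatFit(m, batch), "f003.*B.*completenessFilter")
  m2 <- randomMatrix(10, 8, 2)
  m2["f002", 5:7] <- NA  # single observation left in batch B
  expect_error(combatFit(m2, batch), "single observation")
  expect_error(combatFit(randomMatrix(10, 5, 3), rep("A", 5)),
               "single batch")
  expect_error(combatFit(randomMatrix(10, 3, 3), c("A", "A", "B")),
               "fewer than 2 samples")
})

test_that("identity limit: null batch parameters reproduce the input", {
  m <- randomMatrix(15, 10, 4)
  batch <- rep(c("A", "B"), each = 5)
  G <- nrow(m)
  var.pooled <- apply(m, 1, function(v) mean((v - mean(v))^2))
  stand.mean <- matrix(rowMeans(m), G, 10)
  s.data <- (m - stand.mean) / sqrt(var.pooled)
  back <- ProteoBatchQC:::.combatBacktransform(
    s.data, batch, c("A", "B"),
    gamma.star = matrix(0, G, 2), delta.star = matrix(1, G, 2),
    var.pooled = var.pooled, stand.mean = stand.mean)
  expect_equal(back, m, tolerance = 1e-12)
})

test_that("batches from one distribution are left nearly untouched", {
  set.seed(21)
  m <- randomMatrix(50, 40, 21)
  batch <- rep(c("A", "B"), each = 20)
  res <- combatFit(m, batch)
  expect_lt(mean(abs(res$adjusted - m)), 0.2)
  d0 <- abs(rowMeans(m[, batch == "A"]) - rowMeans(m[, batch == "B"]))
  d1 <- abs(rowMeans(res$adjusted[, batch == "A"]) -
            rowMeans(res$adjusted[, batch == "B"]))
  # the location-scale model rescales per-batch residuals, which can
  # inflate near-zero differences; the reference implementation behaves
  # identically (checked above to 1e-6), so assert the robust properties
  expect_gte(mean(d1 <= d0 + 1e-12), 0.75)
  expect_lt(median(d1 / d0), 1)
})

test_that("EB adjustment tolerates scattered missing values", {
  m <- randomMatrix(30, 20, 6, missing = 0.1)
  batch <- rep(c("A", "B"), each = 10)
  keep <- apply(!is.na(m), 1, function(o)
    sum(o[batch == "A"]) >= 2 && sum(o[batch == "B"]) >= 2)
  m <- m[keep, ]
  res <- combatFit(m, batch)
  expect_identical(is.na(res$adjusted), is.na(m))
  d0 <- abs(rowMeans(m[, batch == "A"], na.rm = TRUE) -
            rowMeans(m[, batch == "B"], na.rm = TRUE))
  d1 <- abs(rowMeans(res$adjusted[, batch == "A"], na.rm = TRUE) -
            rowMeans(res$adjusted[, batch == "B"], na.rm = TRUE))
  expect_gt(mean(d1 <= d0 + 1e-12), 0.8)
})

test_that("the BatchExperiment interface wires the batch factor through", {
  sim <- simulateExperiment(simulationSpec(
    nProteins = 20, peptidesPerProtein = 1, nSamples = 30, nBatches = 2,
    driftAmplitude = 0, nReplicateSpecimens = 0, spikeInCount = 0,
    seed = 5))
  res <- combatAdjust(sim$experiment, "MS_batch", covariates = "group")
  expect_s4_class(res$corrected, "BatchExperiment")
  stages <- vapply(processingLog(res$corrected), `[[`, "", "stage")
  expect_true("combat" %in% stages)
  m0 <- intensityMatrix(sim$experiment)
  m1 <- intensityMatrix(res$corrected)
  b <- sampleFactor(sim$experiment, "MS_batch")
  d0 <- abs(rowMeans(m0[, b == "B1"]) - rowMeans(m0[, b == "B2"]))
  d1 <- abs(rowMeans(m1[, b == "B1"]) - rowMeans(m1[, b == "B2"]))
  expect_lt(median(d1), median(d0))
})
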