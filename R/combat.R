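## Parametric empirical-Bayes location-scale batch adjustment.
##
## Model: after per-feature standardisation (grand mean + optional covariate
## design, pooled variance), each feature g in batch b has location gamma_gb
## and scale delta2_gb. A normal prior on the locations and an inverse-gamma
## prior on the scales are moment-matched per batch across features, and the
## standard conditional-posterior updates are iterated to tolerance. The
## shrunk estimates are removed and the data back-transformed. This requires
## every feature to be quantified in every batch (use completenessFilter()
## with scope "per_batch" first); median centering is the robust alternative
## when missingness is batch-specific.

.postmean <- function(g.hat, g.bar, n, d.old, t2) {
  (t2 * n * g.hat + d.old * g.bar) / (t2 * n + d.old)
}

.postvar <- function(sum2, n, a, b) {
  (0.5 * sum2 + b) / (n / 2 + a - 1)
}

## moment-matched inverse-gamma hyperparameters
.aprior <- function(delta.hat) {
  m <- mean(delta.hat); s2 <- stats::var(delta.hat)
  (2 * s2 + m^2) / s2
}
.bprior <- function(delta.hat) {
  m <- mean(delta.hat); s2 <- stats::var(delta.hat)
  (m * s2 + m^3) / s2
}

## iterate conditional posteriors for one batch; sdat: features x batch cols
.ebIterate <- function(sdat, g.hat, d.hat, g.bar, t2, a, b,
                       conv = 1e-4, maxIter = 100L) {
  n <- rowSums(!is.na(sdat))
  g.old <- g.hat
  d.old <- d.hat
  change <- 1
  count <- 0L
  while (change > conv && count < maxIter) {
    g.new <- .postmean(g.hat, g.bar, n, d.old, t2)
    sum2 <- rowSums((sdat - g.new)^2, na.rm = TRUE)
    d.new <- .postvar(sum2, n, a, b)
    change <- max(abs(g.new - g.old) / g.old, abs(d.new - d.old) / d.old)
    g.old <- g.new
    d.old <- d.new
    count <- count + 1L
  }
  list(gamma.star = g.old, delta.star = d.old, iterations = count,
       change = change)
}

#' Empirical-Bayes location-scale batch adjustment
#'
#' Parametric empirical-Bayes adjustment of discrete batch effects in both
#' location and scale, with optional categorical covariates protecting
#' biological group differences. Every feature must be observed at least
#' twice in every batch; features missing from an entire batch are a hard
#' error naming the offending (feature, batch) pairs — filter with
#' [completenessFilter()] (`scope = "per_batch"`) first, or use the
#' missingness-robust [centerDiscrete()] instead.
#'
#' @inheritParams correctDrift
#' @param covariates optional character vector of biological factor names
#'   (colData columns) to include in the standardisation design.
#' @param tol convergence tolerance on the maximum relative change of the
#'   shrunk parameters.
#' @param maxIter maximum conditional-posterior sweeps per batch.
#' @return list with `corrected` (a [BatchExperiment-class]) and `params`
#'   (a [CombatParams-class]).
#' @export
combatAdjust <- function(x, batchFactor, covariates = NULL, tol = 1e-4,
                         maxIter = 100L) {
  stopifnot(is(x, "BatchExperiment"))
  batch <- .batchLevels(x, batchFactor)
  m <- intensityMatrix(x)
  res <- combatFit(m, batch,
                   covariateData = if (length(covariates)) {
                     df <- as.data.frame(colData(x)[, covariates,
                                                    drop = FALSE])
                     df[] <- lapply(df, factor)
                     df
                   } else NULL,
                   tol = tol, maxIter = maxIter)
  corrected <- .updateIntensities(
    x, res$adjusted, "combat",
    list(batch_factor = batchFactor,
         covariates = if (length(covariates)) covariates else NULL,
         tolerance = tol))
  list(corrected = corrected, params = res$params)
}

#' @rdname combatAdjust
#' @param m numeric features x samples matrix (log2 scale, `NA` = missing).
#' @param batch character/factor of per-sample batch levels.
#' @param covariateData optional `data.frame` of per-sample categorical
#'   covariates.
#' @return `combatFit` returns a list with `adjusted` (matrix) and `params`.
#' @export
combatFit <- function(m, batch, covariateData = NULL, tol = 1e-4,
                      maxIter = 100L) {
  stopifnot(is.matrix(m))
  batch <- as.character(batch)
  levels_b <- unique(batch)
  n.batch <- length(levels_b)
  if (n.batch < 2)
    stop("batch adjustment is degenerate with a single batch")
  n.array <- ncol(m)
  n.batches <- vapply(levels_b, function(b) sum(batch == b), integer(1))
  if (any(n.batches < 2))
    stop("batch(es) with fewer than 2 samples: ",
         paste(levels_b[n.batches < 2], collapse = ", "))
  if (nrow(m) < 2)
    stop("empirical-Bayes shrinkage needs >= 2 features")

  ## completeness precondition: >= 2 observations per feature per batch
  counts <- vapply(levels_b, function(b)
    rowSums(!is.na(m[, batch == b, drop = FALSE])), numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m),
                   dimnames = list(rownames(m), levels_b))
  absent <- which(counts == 0, arr.ind = TRUE)
  if (nrow(absent)) {
    pairs <- paste0("(", rownames(m)[absent[, 1]], ", ",
                    levels_b[absent[, 2]], ")")
    stop("feature(s) missing from an entire batch: ",
         paste(utils::head(pairs, 5), collapse = ", "),
         if (nrow(absent) > 5) sprintf(" and %d more", nrow(absent) - 5),
         "; apply completenessFilter(scope = 'per_batch') first")
  }
  sparse <- which(counts == 1, arr.ind = TRUE)
  if (nrow(sparse))
    stop("feature(s) with a single observation in a batch (cannot ",
         "estimate scale): ",
         paste(utils::head(rownames(m)[sparse[, 1]], 5), collapse = ", "))

  batch.design <- vapply(levels_b, function(b) as.numeric(batch == b),
                         numeric(n.array))
  design <- batch.design
  if (!is.null(covariateData)) {
    mm <- stats::model.matrix(~., data = covariateData)
    design <- cbind(batch.design, mm[, -1, drop = FALSE])
    if (qr(design)$rank < ncol(design))
      stop("covariate design is confounded with batch")
  }

  has_na <- anyNA(m)
  if (!has_na) {
    B.hat <- solve(crossprod(design), t(design) %*% t(m))
    resid <- m - t(design %*% B.hat)
    var.pooled <- as.numeric(resid^2 %*% rep(1 / n.array, n.array))
  } else {
    B.hat <- matrix(NA_real_, ncol(design), nrow(m))
    var.pooled <- numeric(nrow(m))
    for (g in seq_len(nrow(m))) {
      obs <- which(!is.na(m[g, ]))
      Xo <- design[obs, , drop = FALSE]
      fit <- stats::lm.fit(Xo, m[g, obs])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      B.hat[, g] <- beta
      var.pooled[g] <- mean((m[g, obs] - Xo %*% beta)^2)
    }
  }
  if (any(var.pooled <= 0))
    stop("feature(s) with zero pooled variance: ",
         paste(rownames(m)[var.pooled <= 0], collapse = ", "))

  grand.mean <- crossprod(n.batches / n.array,
                          B.hat[seq_len(n.batch), , drop = FALSE])
  stand.mean <- t(grand.mean) %*% t(rep(1, n.array))
  if (ncol(design) > n.batch) {
    tmp <- design
    tmp[, seq_len(n.batch)] <- 0
    stand.mean <- stand.mean + t(tmp %*% B.hat)
  }
  s.data <- (m - stand.mean) / (sqrt(var.pooled) %*% t(rep(1, n.array)))

  gamma.hat <- vapply(levels_b, function(b)
    rowMeans(s.data[, batch == b, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m)))
  delta.hat <- vapply(levels_b, function(b)
    apply(s.data[, batch == b, drop = FALSE], 1, stats::var, na.rm = TRUE),
    numeric(nrow(m)))
  gamma.hat <- matrix(gamma.hat, nrow = nrow(m),
                      dimnames = list(rownames(m), levels_b))
  delta.hat <- matrix(delta.hat, nrow = nrow(m),
                      dimnames = list(rownames(m), levels_b))

  gamma.bar <- colMeans(gamma.hat)
  t2 <- apply(gamma.hat, 2, stats::var)
  a.prior <- apply(delta.hat, 2, .aprior)
  b.prior <- apply(delta.hat, 2, .bprior)

  gamma.star <- gamma.hat
  delta.star <- delta.hat
  iterations <- integer(n.batch)
  for (j in seq_len(n.batch)) {
    sdat <- s.data[, batch == levels_b[j], drop = FALSE]
    sol <- .ebIterate(sdat, gamma.hat[, j], delta.hat[, j], gamma.bar[j],
                      t2[j], a.prior[j], b.prior[j], conv = tol,
                      maxIter = maxIter)
    gamma.star[, j] <- sol$gamma.star
    delta.star[, j] <- sol$delta.star
    iterations[j] <- sol$iterations
  }

  adjusted <- .combatBacktransform(s.data, batch, levels_b, gamma.star,
                                   delta.star, var.pooled, stand.mean)
  dimnames(adjusted) <- dimnames(m)
  params <- new("CombatParams",
                grandMean = as.numeric(grand.mean),
                pooledVar = var.pooled,
                gammaHat = gamma.hat, deltaHat = delta.hat,
                gammaBar = gamma.bar, t2 = t2,
                aPrior = a.prior, bPrior = b.prior,
                gammaStar = gamma.star, deltaStar = delta.star,
                iterations = iterations, tolerance = tol)
  list(adjusted = adjusted, params = params)
}

## remove shrunk batch location/scale on the standardised scale, then
## restore pooled variance and standardisation mean
.combatBacktransform <- function(s.data, batch, levels_b, gamma.star,
                                 delta.star, var.pooled, stand.mean) {
  bayes <- s.data
  for (j in seq_along(levels_b)) {
    idx <- which(batch == levels_b[j])
    bayes[, idx] <- (bayes[, idx, drop = FALSE] - gamma.star[, j]) /
      sqrt(delta.star[, j])
  }
  bayes * (sqrt(var.pooled) %*% t(rep(1, ncol(s.data)))) + stand.mean
}
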