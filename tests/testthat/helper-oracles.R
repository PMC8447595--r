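# Independent brute-force oracles. These re-derive expected values through
# a different code path than the implementation (explicit normal equations,
# naive agglomeration, direct enumeration) and must stay independent of the
# package internals.

# local polynomial regression via explicit weighted normal equations in the
# RAW predictor basis (the implementation solves a centered basis per point)
bruteLocalRegression <- function(x, y, span, degree) {
  n <- length(x)
  q <- min(max(ceiling(span * n), degree + 2), n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    if (h == 0) return(y[i])
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    use <- w > 0
    X <- outer(x[use], 0:degree, `^`)
    W <- diag(w[use], nrow = sum(use))
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[use])
    sum(beta * x[i]^(0:degree))
  }, numeric(1))
}

# quantile normalization oracle: per-sample interpolated quantile functions
# on a common grid, reference = per-rank mean, values mapped at fractional
# ranks (average ranks for ties)
bruteQuantileNormalize <- function(m) {
  nobs <- colSums(!is.na(m))
  grid_n <- max(nobs)
  p <- (seq_len(grid_n) - 1) / (grid_n - 1)
  qf <- sapply(seq_len(ncol(m)), function(j) {
    v <- sort(m[!is.na(m[, j]), j])
    stats::approx((seq_along(v) - 1) / (length(v) - 1), v, xout = p,
                  rule = 2)$y
  })
  ref <- rowMeans(qf)
  out <- m
  for (j in seq_len(ncol(m))) {
    obs <- which(!is.na(m[, j]))
    fr <- (rank(m[obs, j], ties.method = "average") - 1) / (length(obs) - 1)
    out[obs, j] <- stats::approx(p, ref, xout = fr, rule = 2)$y
  }
  out
}

# O(n^3) average-linkage agglomeration; returns sorted merge heights
bruteAverageLinkageHeights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestv <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        v <- mean(d[clusters[[i]], clusters[[j]]])
        if (v < bestv) {
          bestv <- v
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bestv)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# type-7 quartiles and Tukey fences by direct enumeration
bruteQuartiles <- function(v) {
  v <- sort(v)
  n <- length(v)
  q <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  c(q1 = q(0.25), med = q(0.5), q3 = q(0.75))
}

bruteOutlierCount <- function(v) {
  q <- bruteQuartiles(v)
  iqr <- q["q3"] - q["q1"]
  sum(v < q["q1"] - 1.5 * iqr | v > q["q3"] + 1.5 * iqr)
}
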