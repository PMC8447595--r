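## Principal variance component analysis.
##
## PCA compresses the matrix into leading components; a random-intercept
## mixed model per retained component attributes each component's variance
## to the annotated factors (and optionally their pairwise interactions)
## plus a residual; the per-component proportions are averaged with
## eigenvalue weights. The result is a one-line numeric answer to "how much
## of the variance is technical?".

#' Principal variance component analysis
#'
#' For the complete-feature, feature-centered matrix: (1) retain the
#' smallest set of leading principal components whose cumulative variance
#' reaches `varianceThreshold`; (2) for each retained component, fit a
#' restricted-maximum-likelihood random-intercepts model of the component
#' scores on all requested factors (and pairwise interactions), and extract
#' the variance components plus residual; (3) normalise within component and
#' average across components with eigenvalue-fraction weights.
#'
#' With a partial threshold the decomposition describes the leading,
#' structured part of the variance only — strong batch structure concentrates
#' in the top components, so the batch share among retained components is
#' larger than its share of total variance. Set `varianceThreshold = 1` to
#' decompose the total variance.
#'
#' @param x a [BatchExperiment-class].
#' @param factors character vector of annotation factor names (each with
#'   >= 2 levels present).
#' @param includeInteractions logical, add pairwise `A:B` random intercepts.
#' @param varianceThreshold cumulative eigenvalue fraction that decides how
#'   many components are modelled, in (0, 1].
#' @inheritParams pcaScores
#' @return a [PvcaResult-class]; proportions sum to 1.
#' @export
pvca <- function(x, factors, includeInteractions = TRUE,
                 varianceThreshold = 0.6,
                 missingPolicy = c("complete_features", "error")) {
  stopifnot(is(x, "BatchExperiment"), length(factors) >= 1)
  stopifnot(varianceThreshold > 0, varianceThreshold <= 1)
  m <- intensityMatrix(x)
  cf <- .completeFeatures(m, missingPolicy, "PVCA")
  if (nrow(cf$m) < 2) stop("PVCA needs >= 2 complete features")

  fac <- lapply(factors, function(f) factor(sampleFactor(x, f)))
  names(fac) <- factors
  for (f in factors)
    if (nlevels(fac[[f]]) < 2)
      stop("factor '", f, "' has fewer than 2 levels present")
  ## identical sample partitions cannot be separated by the model
  if (length(factors) > 1) {
    for (i in seq_len(length(factors) - 1)) {
      for (j in seq(i + 1, length(factors))) {
        if (.samePartition(fac[[i]], fac[[j]]))
          stop("factors '", factors[i], "' and '", factors[j],
               "' are fully confounded (identical sample partitions) ",
               "and cannot be separated")
      }
    }
  }

  centered <- cf$m - rowMeans(cf$m)
  pc <- stats::prcomp(t(centered), center = FALSE)
  ev <- pc$sdev^2
  ev_frac <- ev / sum(ev)
  cum <- cumsum(ev_frac)
  k <- which(cum >= varianceThreshold - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  ## drop numerically null components (rank boundary)
  k <- min(k, max(which(ev > max(ev) * 1e-12)))

  terms <- factors
  if (includeInteractions && length(factors) > 1) {
    pairs <- utils::combn(factors, 2)
    terms <- c(terms, apply(pairs, 2, paste, collapse = ":"))
  }
  sources <- c(terms, "residual")

  df <- as.data.frame(fac)
  names(df) <- factors
  form <- stats::as.formula(paste(
    "score ~", paste(sprintf("(1 | %s)", terms), collapse = " + ")))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.grad = "ignore",
                            check.conv.singular = "ignore",
                            check.conv.hess = "ignore")

  props <- matrix(0, nrow = k, ncol = length(sources),
                  dimnames = list(NULL, sources))
  for (i in seq_len(k)) {
    df$score <- pc$x[, i]
    vc <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(form, data = df, REML = TRUE, control = ctrl)))
      vcs <- as.data.frame(lme4::VarCorr(fit))
      v <- vcs$vcov
      names(v) <- vcs$grp
      v
    }, error = function(e) NULL)
    if (is.null(vc)) {
      props[i, "residual"] <- 1
      next
    }
    out <- numeric(length(sources))
    names(out) <- sources
    out["residual"] <- vc[["Residual"]]
    for (tm in terms) {
      key <- if (tm %in% names(vc)) tm else gsub(":", ".", tm)
      if (key %in% names(vc)) out[tm] <- vc[[key]]
    }
    out <- pmax(out, 0)
    props[i, ] <- out / sum(out)
  }

  w <- ev_frac[seq_len(k)] / sum(ev_frac[seq_len(k)])
  weighted <- as.numeric(w %*% props)
  weighted <- weighted / sum(weighted)
  new("PvcaResult",
      table = data.frame(source = sources, proportion = weighted,
                         stringsAsFactors = FALSE),
      nComponents = as.integer(k),
      varianceThreshold = varianceThreshold,
      eigenFractions = ev_frac[seq_len(k)],
      nFeaturesUsed = nrow(cf$m),
      nFeaturesDropped = as.integer(cf$nDropped))
}

## TRUE when two factors induce the same partition of samples
.samePartition <- function(a, b) {
  ia <- as.integer(factor(a))
  ib <- as.integer(factor(b))
  all(tapply(ib, ia, function(v) length(unique(v))) == 1) &&
    all(tapply(ia, ib, function(v) length(unique(v))) == 1)
}
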