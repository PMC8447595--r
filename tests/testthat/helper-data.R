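# Shared constructors for small in-code fixtures.

# BatchExperiment from a plain matrix + batch vector (+ optional extras)
makeBE <- function(m, batch, group = NULL, replicate = NULL,
                   run_order = seq_len(ncol(m)), proteins = NULL) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
  ann <- data.frame(sample_id = colnames(m), run_order = run_order,
                    batch = batch, stringsAsFactors = FALSE)
  bio <- character(0)
  if (!is.null(group)) {
    ann$group <- group
    bio <- "group"
  }
  repcol <- NULL
  if (!is.null(replicate)) {
    ann$replicate_group <- replicate
    repcol <- "replicate_group"
  }
  fa <- if (!is.null(proteins))
    data.frame(feature_id = rownames(m), protein_id = proteins,
               is_spike_in = FALSE, stringsAsFactors = FALSE)
  else NULL
  BatchExperiment(m, ann, batchFactors = "batch", bioFactors = bio,
                  replicateGroup = repcol, featureAnnotation = fa)
}

# seeded random matrix with optional missingness
randomMatrix <- function(nr, nc, seed, missing = 0, mean = 20, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, mean, sd), nr, nc,
              dimnames = list(sprintf("f%03d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  if (missing > 0) m[runif(nr * nc) < missing] <- NA
  m
}
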