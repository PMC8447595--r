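## Delimited-text I/O and long <-> wide conversion.
##
## On-disk conventions: tab-separated by default; "NA" and the empty string
## are missing-value tokens. In long form a missing measurement is an ABSENT
## record; in wide form it is an NA cell. Sentinel zeros are never written.

#' Read a long-format intensity table
#'
#' Reads tidy `(feature_id, sample_id, intensity)` records. Rows whose
#' intensity is a missing token are treated as absent measurements and
#' dropped; duplicated `(feature, sample)` pairs are an integrity error.
#'
#' @param path file path.
#' @param featureCol,sampleCol,intensityCol column names in the header.
#' @param sep field delimiter (default tab).
#' @param naStrings tokens read as missing.
#' @return `data.frame` with columns `feature_id`, `sample_id`, `intensity`
#'   (log2 scale), one row per observed measurement.
#' @export
readLongTable <- function(path, featureCol = "feature_id",
                          sampleCol = "sample_id",
                          intensityCol = "intensity",
                          sep = "\t", naStrings = c("NA", "")) {
  df <- .readDelim(path, sep, naStrings)
  need <- c(featureCol, sampleCol, intensityCol)
  if (!all(need %in% names(df)))
    stop("long table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  out <- data.frame(
    feature_id = as.character(df[[featureCol]]),
    sample_id = as.character(df[[sampleCol]]),
    intensity = .asIntensity(df[[intensityCol]], path),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  validateLongTable(out)
}

## shared low-level reader with line-numbered malformed-row errors
.readDelim <- function(path, sep = "\t", naStrings = c("NA", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            blank.lines.skip = FALSE)
  keep <- !is.na(nf)
  if (length(unique(nf[keep & nf > 0])) > 1) {
    bad <- which(nf != nf[1] & nf > 0)[1]
    stop("malformed row in ", path, " at line ", bad,
         ": expected ", nf[1], " fields, found ", nf[bad])
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = naStrings, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

.asIntensity <- function(v, path) {
  if (is.character(v)) {
    suppressWarnings(num <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("non-numeric intensity in ", path, " (data row ", bad[1],
           "): '", v[bad[1]], "'")
    v <- num
  }
  as.numeric(v)
}

#' Validate a long intensity table
#'
#' Enforces the long-table invariants: unique `(feature_id, sample_id)`
#' pairs and finite intensities.
#'
#' @param df `data.frame` with `feature_id`, `sample_id`, `intensity`.
#' @return the validated `data.frame`, invisibly unchanged.
#' @export
validateLongTable <- function(df) {
  stopifnot(all(c("feature_id", "sample_id", "intensity") %in% names(df)))
  key <- paste(df$feature_id, df$sample_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (feature_id, sample_id) pair: (",
         df$feature_id[dup[1]], ", ", df$sample_id[dup[1]], ")")
  }
  bad <- which(!is.finite(df$intensity))
  if (length(bad))
    stop("non-finite intensity for (", df$feature_id[bad[1]], ", ",
         df$sample_id[bad[1]], ")")
  df
}

#' Convert between long records and a wide matrix
#'
#' The two forms are lossless up to record order: absent long records
#' correspond exactly to `NA` cells in the wide matrix. Row and column order
#' of the wide matrix follows first appearance in the long table.
#'
#' @param df long `data.frame` (`feature_id`, `sample_id`, `intensity`).
#' @return `longToWide`: numeric matrix, features x samples.
#' @export
longToWide <- function(df) {
  df <- validateLongTable(df)
  f <- unique(df$feature_id)
  s <- unique(df$sample_id)
  m <- matrix(NA_real_, length(f), length(s), dimnames = list(f, s))
  m[cbind(match(df$feature_id, f), match(df$sample_id, s))] <- df$intensity
  m
}

#' @rdname longToWide
#' @param m numeric matrix with feature rownames and sample colnames.
#' @return `wideToLong`: long `data.frame`, one row per non-`NA` cell, in
#'   column-major order.
#' @export
wideToLong <- function(m) {
  stopifnot(is.matrix(m))
  if (length(m) == 0 || all(is.na(m))) {
    return(data.frame(feature_id = character(0), sample_id = character(0),
                      intensity = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- which(!is.na(m), arr.ind = TRUE)
  data.frame(
    feature_id = rownames(m)[idx[, 1]],
    sample_id = colnames(m)[idx[, 2]],
    intensity = m[idx],
    stringsAsFactors = FALSE
  )
}

#' Read a wide intensity matrix
#'
#' First column holds feature identifiers; remaining columns are samples.
#'
#' @inheritParams readLongTable
#' @return numeric matrix, features x samples, `NA` = missing.
#' @export
readWideMatrix <- function(path, sep = "\t", naStrings = c("NA", "")) {
  df <- .readDelim(path, sep, naStrings)
  if (ncol(df) < 2) stop("wide matrix ", path, " needs >= 2 columns")
  f <- as.character(df[[1]])
  if (anyDuplicated(f)) stop("duplicate feature_id in ", path, ": ",
                             f[duplicated(f)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- f
  m
}

#' Read sample or feature annotation tables
#'
#' @inheritParams readLongTable
#' @return `readSampleAnnotation`: `data.frame` with `sample_id`, integer
#'   `run_order` and the factor columns. Duplicate sample ids or run orders
#'   are integrity errors (resolve acquisition-timestamp ties upstream).
#' @export
readSampleAnnotation <- function(path, sep = "\t", naStrings = c("NA", "")) {
  df <- .readDelim(path, sep, naStrings)
  if (!all(c("sample_id", "run_order") %in% names(df)))
    stop("sample annotation ", path,
         " must have 'sample_id' and 'run_order' columns")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path, ": ",
         df$sample_id[duplicated(df$sample_id)][1])
  ro <- df$run_order
  if (anyNA(ro) || any(ro != as.integer(ro)))
    stop("run_order must be integer ranks in ", path)
  if (anyDuplicated(ro))
    stop("duplicate run_order in ", path, ": ", ro[duplicated(ro)][1],
         " (resolve acquisition ties before import)")
  df$run_order <- as.integer(ro)
  df
}

#' @rdname readSampleAnnotation
#' @return `readFeatureAnnotation`: `data.frame` with `feature_id`,
#'   `protein_id`, logical `is_spike_in`.
#' @export
readFeatureAnnotation <- function(path, sep = "\t", naStrings = c("NA", "")) {
  df <- .readDelim(path, sep, naStrings)
  if (!all(c("feature_id", "protein_id") %in% names(df)))
    stop("feature annotation ", path,
         " must have 'feature_id' and 'protein_id' columns")
  df$feature_id <- as.character(df$feature_id)
  df$protein_id <- as.character(df$protein_id)
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id in ", path)
  if (!"is_spike_in" %in% names(df)) df$is_spike_in <- FALSE
  df$is_spike_in <- as.logical(df$is_spike_in) %in% TRUE
  df
}

#' Read factor roles from a YAML declaration
#'
#' The annotation table itself does not say which columns are technical;
#' roles are declared in a small YAML file with keys `batch`, `biological`
#' and (optionally) `replicate`.
#'
#' @param path YAML file path.
#' @return list with elements `batch` (character), `biological` (character)
#'   and `replicate` (string or `NULL`).
#' @export
readFactorRoles <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    batch = as.character(y$batch %||% character(0)),
    biological = as.character(y$biological %||% character(0)),
    replicate = if (is.null(y$replicate)) NULL else as.character(y$replicate)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BatchExperiment from delimited files
#'
#' @param intensityPath path to a long or wide intensity table.
#' @param sampleAnnotationPath path to the sample annotation TSV.
#' @param roles factor-role declaration: a list as returned by
#'   [readFactorRoles()] or the path of the YAML file.
#' @param featureAnnotationPath optional feature annotation TSV.
#' @param format `"long"` or `"wide"`.
#' @inheritParams readLongTable
#' @return a [BatchExperiment-class].
#' @export
readBatchExperiment <- function(intensityPath, sampleAnnotationPath, roles,
                                featureAnnotationPath = NULL,
                                format = c("long", "wide"), sep = "\t",
                                naStrings = c("NA", "")) {
  format <- match.arg(format)
  if (is.character(roles) && length(roles) == 1) roles <- readFactorRoles(roles)
  m <- if (format == "long") {
    longToWide(readLongTable(intensityPath, sep = sep, naStrings = naStrings))
  } else {
    readWideMatrix(intensityPath, sep = sep, naStrings = naStrings)
  }
  ann <- readSampleAnnotation(sampleAnnotationPath, sep = sep,
                              naStrings = naStrings)
  fa <- if (!is.null(featureAnnotationPath)) {
    readFeatureAnnotation(featureAnnotationPath, sep = sep,
                          naStrings = naStrings)
  } else NULL
  BatchExperiment(m, ann, batchFactors = roles$batch,
                  bioFactors = roles$biological,
                  replicateGroup = roles$replicate,
                  featureAnnotation = fa)
}

#' Write intensity tables
#'
#' @param x a [BatchExperiment-class], long `data.frame` or wide matrix.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
writeLongTable <- function(x, path, sep = "\t") {
  df <- if (is(x, "BatchExperiment")) wideToLong(intensityMatrix(x))
        else if (is.matrix(x)) wideToLong(x) else validateLongTable(x)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLongTable
#' @export
writeWideMatrix <- function(x, path, sep = "\t") {
  m <- if (is(x, "BatchExperiment")) intensityMatrix(x)
       else if (is.matrix(x)) x else longToWide(x)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform raw-scale intensities
#'
#' Applies `log_base(x + offset)` cellwise; missing cells stay missing. The
#' whole downstream workflow assumes log2-scale data, so this is typically
#' the first operation after import of raw-scale quantities.
#'
#' @param x a [BatchExperiment-class] or numeric matrix on the raw scale.
#' @param base logarithm base (default 2).
#' @param offset non-negative shift added before taking the log.
#' @return object of the same class, transformed.
#' @export
logTransformIntensities <- function(x, base = 2, offset = 0) {
  stopifnot(offset >= 0, base > 1)
  m <- if (is(x, "BatchExperiment")) intensityMatrix(x) else x
  stopifnot(is.matrix(m))
  shifted <- m + offset
  bad <- which(!is.na(shifted) & shifted <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive intensity after offset for (",
         rownames(m)[bad[1, 1]], ", ", colnames(m)[bad[1, 2]], ")")
  out <- log(shifted, base = base)
  if (is(x, "BatchExperiment")) {
    .updateIntensities(x, out, "log_transform",
                       list(base = base, offset = offset))
  } else out
}
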