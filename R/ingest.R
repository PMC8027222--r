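#' Read a gene-level count matrix
#'
#' Reads a genes x samples matrix of non-negative integer counts from either
#' a dense tab-separated file (first column `gene_id`, one column per sample)
#' or a MatrixMarket sparse file accompanied by `rows.txt` / `cols.txt` id
#' files in the same directory.
#'
#' @param path Path to the counts file (`.tsv` or `.mtx`).
#' @param format Either `"tsv"` or `"mtx"`. Defaults to the file extension.
#' @return An integer matrix with gene ids as rownames and sample ids as
#'   colnames, in file order.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (missing(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("counts TSV needs a gene_id column and >= 2 samples")
    gene_ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- gene_ids
  } else {
    dir <- dirname(path)
    rows_f <- file.path(dir, "rows.txt")
    cols_f <- file.path(dir, "cols.txt")
    if (!file.exists(rows_f) || !file.exists(cols_f)) {
      stop("MTX counts require rows.txt and cols.txt next to ", path)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rows_f)
    colnames(m) <- readLines(cols_f)
  }
  validate_counts(m)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]. The TSV dialect is canonical: tab-separated,
#' UTF-8, a `gene_id` first column, no quoting, so that
#' `write_counts(read_counts(f))` round-trips byte-identically.
#'
#' @param counts Validated integer count matrix with dimnames.
#' @param path Output path; for `"mtx"`, `rows.txt`/`cols.txt` are written
#'   alongside.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  counts <- validate_counts(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(counts), file.path(dir, "rows.txt"))
    writeLines(colnames(counts), file.path(dir, "cols.txt"))
  }
  invisible(path)
}

# Shared validation for count matrices: unique dimnames, non-negative
# integral entries, at least 1 gene and 2 samples.
validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (nrow(counts) < 1L || ncol(counts) < 2L) {
    stop("need at least 1 gene and 2 samples")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid count (negative or non-integer) at gene ",
         rownames(counts)[bad[1L, 1L]], ", sample ",
         colnames(counts)[bad[1L, 2L]])
  }
  storage.mode(counts) <- "double"
  counts
}

#' Default condition alias map
#'
#' Treatment labels differ between assays ("SIP", "pheromone", ...); this map
#' normalizes them to the two canonical levels `control` and `treated`.
#'
#' @return Named character vector mapping raw labels to canonical labels.
#' @export
default_condition_aliases <- function() {
  c(control = "control", ctrl = "control", untreated = "control",
    mock = "control",
    treated = "treated", sip = "treated", `sip-` = "treated",
    `sip+` = "treated", pheromone = "treated", filtrate = "treated")
}

# "15min" -> 15, "1h" -> 60, "0h" -> 0, bare numbers are taken as minutes.
parse_timepoint <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  needs <- is.na(out)
  if (any(needs)) {
    m <- regmatches(x[needs],
                    regexec("^([0-9]*\\.?[0-9]+)\\s*(min|m|h|hr|hrs|hour|hours)$",
                            tolower(x[needs])))
    val <- vapply(m, function(g) {
      if (length(g) == 0L) return(NA_real_)
      v <- as.numeric(g[2L])
      if (g[3L] %in% c("min", "m")) v else v * 60
    }, numeric(1))
    out[needs] <- val
  }
  if (anyNA(out)) {
    stop("cannot parse timepoint label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `dataset`, `mating_type`,
#' `timepoint`, `condition` and `replicate` (an `experiment_batch` column is
#' optional and defaults to the dataset id). Timepoints are parsed to minutes
#' and the table is returned with timepoints ordered by time value.
#'
#' @param path Path to the metadata TSV.
#' @param condition_aliases Named map from raw condition labels to
#'   `control`/`treated`; see [default_condition_aliases()].
#' @return A `sample_table` data.frame with an added numeric `time_min`
#'   column and `condition` normalized to `control`/`treated`.
#' @export
read_samples <- function(path, condition_aliases = default_condition_aliases()) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_table(df, condition_aliases = condition_aliases)
}

#' Construct and validate a sample table
#'
#' @param df A data.frame with the columns documented in [read_samples()].
#' @param condition_aliases Named condition alias map.
#' @return A validated `sample_table` data.frame.
#' @export
sample_table <- function(df, condition_aliases = default_condition_aliases()) {
  required <- c("sample_id", "dataset", "mating_type", "timepoint",
                "condition", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("sample table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  cond_raw <- tolower(trimws(as.character(df$condition)))
  unknown <- setdiff(unique(cond_raw), names(condition_aliases))
  if (length(unknown) > 0L) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  }
  df$condition <- unname(condition_aliases[cond_raw])
  df$time_min <- parse_timepoint(df$timepoint)
  if (!("experiment_batch" %in% names(df))) df$experiment_batch <- df$dataset
  df$replicate <- as.integer(df$replicate)
  df <- df[order(df$time_min, df$condition, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Bundle a count matrix with its sample metadata
#'
#' Aligns the columns of `counts` to the row order of `samples` and packages
#' both into an `experiment_bundle`, the unit every downstream stage
#' consumes. Bundling is idempotent.
#'
#' @param counts Count matrix as returned by [read_counts()].
#' @param samples Metadata as returned by [read_samples()].
#' @return An `experiment_bundle` list with elements `counts`, `samples`
#'   and `aligned = TRUE`.
#' @export
bundle <- function(counts, samples) {
  counts <- validate_counts(counts)
  if (!inherits(samples, "sample_table")) samples <- sample_table(samples)
  extra_counts <- setdiff(colnames(counts), samples$sample_id)
  extra_meta <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra_counts) > 0L || length(extra_meta) > 0L) {
    stop("sample id mismatch between counts and metadata; only in counts: [",
         paste(extra_counts, collapse = ", "), "]; only in metadata: [",
         paste(extra_meta, collapse = ", "), "]")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  both <- stats::aggregate(condition ~ time_min, data = samples,
                           FUN = function(x) length(unique(x)))
  if (!any(both$condition >= 2L)) {
    stop("no timepoint has both control and treated samples")
  }
  structure(list(counts = counts, samples = samples, aligned = TRUE),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("experiment_bundle:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  dataset(s):", paste(unique(x$samples$dataset), collapse = ", "), "\n")
  cat("  timepoints (min):",
      paste(sort(unique(x$samples$time_min)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a sample table as TSV
#'
#' @param samples A `sample_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
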