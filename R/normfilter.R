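#' Per-sample library sizes
#'
#' Column totals of the count matrix. An all-zero column is set to 1 (with a
#' warning) so that downstream scaling never divides by zero.
#'
#' @param x An `experiment_bundle` or count matrix.
#' @return Named numeric vector of totals, one per sample.
#' @export
library_sizes <- function(x) {
  counts <- if (inherits(x, "experiment_bundle")) x$counts else x
  sizes <- colSums(counts)
  zero <- sizes == 0
  if (any(zero)) {
    warning("all-zero sample column(s) ",
            paste(colnames(counts)[zero], collapse = ", "),
            "; library size set to 1")
    sizes[zero] <- 1
  }
  sizes
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack), computed
#' with edgeR and rescaled so that their geometric mean is exactly 1. The
#' reference sample and the double trimming of log-ratios and abundances
#' follow the standard TMM construction.
#'
#' @param bundle An `experiment_bundle`.
#' @param trim_logratio Fraction of extreme gene-wise log-ratios trimmed
#'   from each tail (default 0.30).
#' @param trim_abundance Fraction of extreme average abundances trimmed
#'   (default 0.05).
#' @return A `norm_factors` data.frame with columns `sample_id`,
#'   `library_size`, `tmm_factor`, `effective_size`.
#' @export
norm_factors <- function(bundle, trim_logratio = 0.30, trim_abundance = 0.05) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  sizes <- library_sizes(bundle)
  f <- edgeR::calcNormFactors(bundle$counts, lib.size = sizes, method = "TMM",
                              logratioTrim = trim_logratio,
                              sumTrim = trim_abundance)
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample_id = colnames(bundle$counts),
                    library_size = unname(sizes),
                    tmm_factor = unname(f),
                    effective_size = unname(sizes * f),
                    stringsAsFactors = FALSE)
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' Counts per million
#'
#' CPM on effective library sizes (library size times TMM factor). With
#' `log2 = TRUE` the standard moderated log2-CPM is returned, with
#' `prior_count` scaled by relative effective library size, as in edgeR.
#'
#' @param bundle An `experiment_bundle`.
#' @param factors Optional `norm_factors`; computed if `NULL`.
#' @param log2 Return moderated log2-CPM instead of CPM.
#' @param prior_count Average prior count added before the log (default 2).
#' @return genes x samples numeric matrix.
#' @export
cpm_matrix <- function(bundle, factors = NULL, log2 = FALSE, prior_count = 2) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (is.null(factors)) factors <- norm_factors(bundle)
  stopifnot(identical(factors$sample_id, colnames(bundle$counts)))
  edgeR::cpm(bundle$counts, lib.size = factors$library_size,
             norm.factors = factors$tmm_factor,
             log = log2, prior.count = prior_count)
}

#' Low-expression filter
#'
#' A gene is kept when its CPM reaches `cpm_threshold` in at least
#' `min_samples` samples; everything else is "filtered", the status that the
#' cross-dataset integration treats as non-expression. The rule is applied
#' per dataset, so a gene can be filtered in one mating type and tested in
#' the other.
#'
#' @param bundle An `experiment_bundle`.
#' @param factors Optional `norm_factors`.
#' @param cpm_threshold CPM a sample must reach to count (default 1).
#' @param min_samples Number of samples required; defaults to the smallest
#'   (timepoint, condition) group size.
#' @return A `filter_result` list with `kept`, `filtered` (character
#'   vectors of gene ids) and `rule_params`.
#' @export
filter_low <- function(bundle, factors = NULL, cpm_threshold = 1,
                       min_samples = NULL) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (is.null(factors)) factors <- norm_factors(bundle)
  if (is.null(min_samples)) {
    groups <- table(bundle$samples$time_min, bundle$samples$condition)
    min_samples <- min(groups[groups > 0])
  }
  cp <- cpm_matrix(bundle, factors, log2 = FALSE)
  keep <- rowSums(cp >= cpm_threshold) >= min_samples
  structure(list(kept = rownames(bundle$counts)[keep],
                 filtered = rownames(bundle$counts)[!keep],
                 rule_params = list(cpm_threshold = cpm_threshold,
                                    min_samples = as.integer(min_samples))),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("filter_result:", length(x$kept), "kept,", length(x$filtered),
      "filtered (CPM >=", x$rule_params$cpm_threshold, "in >=",
      x$rule_params$min_samples, "samples)\n")
  invisible(x)
}

# Restrict a bundle to a gene subset, preserving order.
subset_genes <- function(bundle, gene_ids) {
  bundle$counts <- bundle$counts[gene_ids, , drop = FALSE]
  bundle
}
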