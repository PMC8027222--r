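#' Read a term-to-gene annotation
#'
#' Two-column TSV (`term_id`, `gene_id`), one gene membership per row, as
#' produced by flattening a GO-style annotation. Optionally a second TSV
#' mapping `term_id` to `term_name`.
#'
#' @param path Path to the two-column annotation TSV (with header).
#' @param names_path Optional term-name TSV (`term_id`, `term_name`).
#' @return Named list of character vectors (term id -> gene ids), with a
#'   `term_names` attribute when names were given.
#' @export
read_annotation <- function(path, names_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation TSV needs term_id and gene_id columns")
  ann <- split(as.character(df[[2L]]), as.character(df[[1L]]))
  ann <- lapply(ann, unique)
  if (!is.null(names_path)) {
    nm <- utils::read.delim(names_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    attr(ann, "term_names") <- stats::setNames(as.character(nm[[2L]]),
                                               as.character(nm[[1L]]))
  }
  ann
}

#' Hypergeometric over-representation test
#'
#' One-sided enrichment of a gene set against each annotation term,
#' restricted to a declared universe (typically the genes surviving the
#' low-expression filter, to guard against detection bias). The p-value is
#' the hypergeometric upper tail `P(X >= k)` for drawing `k` annotated
#' genes in a set of size `n` from a universe of `N` containing `K`
#' annotated genes; BH adjustment is applied within the call (one call per
#' timepoint/direction family).
#'
#' @param gene_set Character vector of genes (must lie in `universe`).
#' @param universe Character vector, the background gene universe.
#' @param annotation Named list of term gene sets (see
#'   [read_annotation()]); memberships outside `universe` are dropped.
#' @param min_term Minimum post-restriction term size to test (default 5).
#' @return An `enrichment_result` data.frame: `term_id`, `overlap`,
#'   `set_size`, `term_size`, `universe_size`, `p`, `padj`, ordered by
#'   `p`.
#' @export
hypergeom_enrich <- function(gene_set, universe, annotation, min_term = 5) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) {
    stop("gene set contains ids outside the universe: ",
         paste(utils::head(setdiff(gene_set, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(gene_set)
  term_genes <- lapply(annotation, function(g) intersect(g, universe))
  K <- vapply(term_genes, length, integer(1))
  keep <- K >= min_term
  term_genes <- term_genes[keep]
  K <- K[keep]
  k <- vapply(term_genes, function(g) length(intersect(g, gene_set)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(term_genes),
                    overlap = unname(k), set_size = n,
                    term_size = unname(K), universe_size = N,
                    p = unname(p), padj = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
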