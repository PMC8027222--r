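#' Simulate a term annotation
#'
#' Random term-to-gene annotation over a synthetic gene universe: term
#' sizes uniform over `term_size_range`, memberships sampled without
#' replacement per term.
#'
#' @param universe_size Number of genes in the universe (default 8000).
#' @param n_terms Number of terms (default 500).
#' @param term_size_range Inclusive term size range (default 5 to 200).
#' @return List with `universe` (gene ids) and `annotation` (named list).
#' @export
simulate_annotation <- function(universe_size = 8000, n_terms = 500,
                                term_size_range = c(5, 200)) {
  universe <- sprintf("u%05d", seq_len(universe_size))
  sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                  replace = TRUE)
  annotation <- lapply(sizes, function(s) sample(universe, s))
  names(annotation) <- sprintf("T%04d", seq_len(n_terms))
  list(universe = universe, annotation = annotation)
}

#' Empirical FDR of the enrichment procedure under random gene sets
#'
#' Draws uniformly random gene sets (hence without any true enrichment)
#' and records, per replicate, the fraction of BH-significant terms that
#' are false calls - which is 1 whenever anything is called and 0
#' otherwise, replicates without rejections contributing zero. The mean of
#' this fraction estimates the procedure's FDR under the global null.
#'
#' @param n_reps Number of replicate draws (default 50).
#' @param set_size Size of each random gene set (default 300).
#' @param alpha BH level (default 0.05).
#' @param universe_size,n_terms,term_size_range Annotation parameters, see
#'   [simulate_annotation()].
#' @param seed Seed for the annotation and all draws.
#' @return List with `fdr` (mean false-call fraction), `se` (Monte-Carlo
#'   standard error), `per_rep` (per-replicate fractions) and `alpha`.
#' @export
run_enrichment_fdr_experiment <- function(n_reps = 50, set_size = 300,
                                          alpha = 0.05,
                                          universe_size = 8000,
                                          n_terms = 500,
                                          term_size_range = c(5, 200),
                                          seed = 1) {
  set.seed(seed)
  ann <- simulate_annotation(universe_size, n_terms, term_size_range)
  per_rep <- vapply(seq_len(n_reps), function(r) {
    gene_set <- sample(ann$universe, set_size)
    res <- hypergeom_enrich(gene_set, ann$universe, ann$annotation)
    n_sig <- sum(res$padj <= alpha)
    if (n_sig > 0) 1 else 0  # every call is false under the global null
  }, numeric(1))
  list(fdr = mean(per_rep),
       se = stats::sd(per_rep) / sqrt(n_reps),
       per_rep = per_rep, alpha = alpha)
}
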