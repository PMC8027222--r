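#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), with input
#' validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-stage decisions with gene-level overall FDR control
#'
#' The overall FDR (OFDR) is the fraction of false positive genes over all
#' rejected genes. It is controlled with a screening/confirmation
#' construction: Stage I applies BH at level `alpha` to the gene-level
#' screening p-values; for the `R` screened genes out of `m`, Stage II
#' judges each per-timepoint confirmation (threshold) test at the level
#' `alpha_confirm = alpha * R / m`, Sidak-corrected across the `T`
#' confirmation hypotheses within a gene (reject when
#' `p <= 1 - (1 - alpha_confirm)^(1/T)`). Genes not passing the screen get
#' no confirmations.
#'
#' Equivalence calls are recorded alongside at unadjusted level
#' `alpha_equiv` per timepoint: they support the other dataset's
#' specificity claim rather than a discovery in this dataset, so they do
#' not consume OFDR budget.
#'
#' @param p_screen Named per-gene screening p-values.
#' @param p_confirm genes x timepoints matrix of threshold-test p-values,
#'   rows aligned to `p_screen`.
#' @param p_equiv Optional genes x timepoints matrix of TOST p-values.
#' @param alpha Target OFDR level (default 0.05).
#' @param alpha_equiv Per-timepoint equivalence level (default 0.05).
#' @return A `decision_table`: list with `genes` (data.frame of `gene_id`,
#'   `screen_padj`, `screened`), logical matrices `de_confirmed` and
#'   `equiv_called` (genes x timepoints), `alpha`, `alpha_confirm`,
#'   `timepoints`.
#' @export
stagewise_decisions <- function(p_screen, p_confirm, p_equiv = NULL,
                                alpha = 0.05, alpha_equiv = 0.05) {
  stopifnot(is.matrix(p_confirm), length(p_screen) == nrow(p_confirm),
            alpha > 0, alpha < 1)
  gene_ids <- names(p_screen)
  if (is.null(gene_ids)) gene_ids <- rownames(p_confirm)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_along(p_screen))
  if (!is.null(p_equiv)) {
    stopifnot(identical(dim(p_equiv), dim(p_confirm)))
  }
  m <- length(p_screen)
  padj <- bh_adjust(as.numeric(p_screen))
  screened <- padj <= alpha
  R <- sum(screened)
  alpha_confirm <- alpha * R / m
  T <- ncol(p_confirm)
  cutoff <- 1 - (1 - alpha_confirm)^(1 / T)
  de_confirmed <- (p_confirm <= cutoff) & screened
  equiv_called <- if (is.null(p_equiv)) {
    matrix(FALSE, m, T, dimnames = dimnames(p_confirm))
  } else {
    p_equiv <= alpha_equiv
  }
  dimnames(de_confirmed) <- dimnames(p_confirm)
  rownames(de_confirmed) <- rownames(equiv_called) <- gene_ids
  timepoints <- suppressWarnings(as.numeric(colnames(p_confirm)))
  structure(list(genes = data.frame(gene_id = gene_ids,
                                    screen_padj = padj,
                                    screened = screened,
                                    stringsAsFactors = FALSE),
                 de_confirmed = de_confirmed,
                 equiv_called = equiv_called,
                 alpha = alpha, alpha_confirm = alpha_confirm,
                 alpha_equiv = alpha_equiv,
                 timepoints = timepoints),
            class = "decision_table")
}

#' @export
print.decision_table <- function(x, ...) {
  cat("decision_table:", nrow(x$genes), "genes,",
      sum(x$genes$screened), "screened,",
      sum(rowSums(x$de_confirmed) > 0), "with confirmed DE calls",
      "(alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Flatten a decision table to a data.frame
#'
#' @param x A `decision_table`.
#' @param ... Unused.
#' @return Wide data.frame with per-timepoint `de_` / `equiv_` columns.
#' @export
as.data.frame.decision_table <- function(x, ...) {
  de <- as.data.frame(x$de_confirmed)
  names(de) <- paste0("de_t", colnames(x$de_confirmed))
  eq <- as.data.frame(x$equiv_called)
  names(eq) <- paste0("equiv_t", colnames(x$equiv_called))
  cbind(x$genes, de, eq, row.names = NULL)
}
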