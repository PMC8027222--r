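#' Per-dataset stage-wise analysis
#'
#' The complete single-dataset arm of the workflow: TMM normalization,
#' low-expression filtering, empirical-Bayes dispersion estimation,
#' cell-means NB GLM fits under the full (timepoint-by-condition) and
#' reduced (timepoint-only) designs, per-timepoint ordinary / threshold /
#' equivalence tests at the fold-change margin, an omnibus LRT screen, and
#' two-stage decisions controlling the gene-level overall FDR at `alpha`.
#'
#' @param bundle An `experiment_bundle`.
#' @param fold_change Fold-change margin (default 3, the log(3) cutoff).
#' @param alpha Target OFDR level (default 0.05).
#' @param cpm_threshold,min_samples Low-expression filter parameters.
#' @param prior_df Dispersion shrinkage prior df (default 10).
#' @param alpha_equiv Per-timepoint equivalence level (default 0.05).
#' @return A `dataset_analysis` list: `factors`, `filter`, `dispersions`,
#'   `fit`, `tests` (long `contrast_results`), `p_screen`, `decisions`,
#'   `design`.
#' @export
analyze_dataset <- function(bundle, fold_change = 3, alpha = 0.05,
                            cpm_threshold = 1, min_samples = NULL,
                            prior_df = 10, alpha_equiv = 0.05) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  factors <- norm_factors(bundle)
  filt <- filter_low(bundle, factors, cpm_threshold = cpm_threshold,
                     min_samples = min_samples)
  kept <- subset_genes(bundle, filt$kept)
  design <- build_design(kept$samples, "timepoint_by_condition")
  design0 <- build_design(kept$samples, "timepoint_only")
  disp <- estimate_dispersions(kept, design, factors, prior_df = prior_df)
  fit <- fit_nbglm(kept, design, disp$tagwise, factors)
  fit0 <- fit_nbglm(kept, design0, disp$tagwise, factors)
  tests <- test_contrasts(fit, fold_change = fold_change)
  p_screen <- stats::setNames(screen_omnibus(fit, fit0), fit$gene_ids)
  tps <- attr(design, "timepoints")
  to_mat <- function(col) {
    m <- matrix(tests[[col]], nrow = length(fit$gene_ids),
                dimnames = list(fit$gene_ids, tps))
    m
  }
  decisions <- stagewise_decisions(p_screen,
                                   p_confirm = to_mat("p_threshold"),
                                   p_equiv = to_mat("p_equiv"),
                                   alpha = alpha, alpha_equiv = alpha_equiv)
  structure(list(factors = factors, filter = filt, dispersions = disp,
                 fit = fit, tests = tests, p_screen = p_screen,
                 decisions = decisions, design = design,
                 samples = bundle$samples,
                 fold_change = fold_change, alpha = alpha),
            class = "dataset_analysis")
}

#' Run the full integrative workflow on two datasets
#'
#' Analyzes each dataset with [analyze_dataset()] and integrates the
#' decisions over the shared timepoints into the SRB / SRP / SRM
#' classification.
#'
#' @param bundle_plus,bundle_minus `experiment_bundle`s for the MT+ and
#'   MT- datasets.
#' @param fold_change,alpha,cpm_threshold,min_samples,prior_df,alpha_equiv
#'   Passed to [analyze_dataset()].
#' @param equivalence_mode,specificity Passed to [classify_genes()].
#' @return A `sip_result` list: `plus`, `minus` (`dataset_analysis`),
#'   `shared` (timepoints), `classification`, `report`.
#' @export
run_sip_pipeline <- function(bundle_plus, bundle_minus, fold_change = 3,
                             alpha = 0.05, cpm_threshold = 1,
                             min_samples = NULL, prior_df = 10,
                             alpha_equiv = 0.05,
                             equivalence_mode = "all_shared_timepoints",
                             specificity = "equivalence") {
  plus <- analyze_dataset(bundle_plus, fold_change, alpha, cpm_threshold,
                          min_samples, prior_df, alpha_equiv)
  minus <- analyze_dataset(bundle_minus, fold_change, alpha, cpm_threshold,
                           min_samples, prior_df, alpha_equiv)
  shared <- shared_timepoints(bundle_plus$samples, bundle_minus$samples)
  cls <- classify_genes(plus$decisions, minus$decisions,
                        plus$filter, minus$filter, shared,
                        equivalence_mode = equivalence_mode,
                        specificity = specificity)
  lfc_at_discovery <- function(analysis, cls) {
    tests <- analysis$tests
    key <- paste(tests$gene_id, tests$time_min)
    idx <- match(paste(cls$gene_id, cls$discovery_timepoint), key)
    stats::setNames(tests$lfc_log2[idx], cls$gene_id)
  }
  report <- classification_report(cls,
                                  lfc_plus = lfc_at_discovery(plus, cls),
                                  lfc_minus = lfc_at_discovery(minus, cls))
  structure(list(plus = plus, minus = minus, shared = shared,
                 classification = cls, report = report,
                 fold_change = fold_change, alpha = alpha),
            class = "sip_result")
}

#' @export
print.sip_result <- function(x, ...) {
  cat("Integrative SIP response workflow (fold change", x$fold_change,
      ", OFDR", x$alpha, ")\n")
  cat("  shared timepoints (min):", paste(x$shared, collapse = ", "), "\n")
  print(x$report$class_counts)
  invisible(x)
}

#' Write workflow results as TSV files
#'
#' Emits, per dataset, the long contrast-test table and the flattened
#' decision table, plus the classification and its evidence table.
#'
#' @param result A `sip_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (side in c("plus", "minus")) {
    a <- result[[side]]
    wt(a$tests, paste0("tests_", side, ".tsv"))
    wt(as.data.frame(a$decisions), paste0("decisions_", side, ".tsv"))
    filt <- data.frame(gene_id = c(a$filter$kept, a$filter$filtered),
                       status = rep(c("kept", "filtered"),
                                    c(length(a$filter$kept),
                                      length(a$filter$filtered))))
    wt(filt, paste0("filter_", side, ".tsv"))
  }
  wt(result$classification, "classification.tsv")
  wt(attr(result$classification, "evidence"), "evidence.tsv")
  invisible(dir)
}
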