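#' Treatment contrasts of a cell-means design
#'
#' One contrast per timepoint at which both conditions are present:
#' treated minus control, i.e. the log fold change attributable to the
#' pheromone at that timepoint, net of the shared time trend.
#'
#' @param design Design matrix from [build_design()] with
#'   `timepoint_by_condition` parameterization.
#' @return Named list of weight vectors (length p), each with a
#'   `timepoint` attribute in minutes.
#' @export
treatment_contrasts <- function(design) {
  cells <- attr(design, "cells")
  tps <- attr(design, "timepoints")
  if (is.null(cells) || is.null(tps)) {
    stop("design lacks cell annotation; use build_design()")
  }
  out <- lapply(tps, function(tp) {
    w <- numeric(ncol(design))
    names(w) <- colnames(design)
    w[paste0("t", tp, "_treated")] <- 1
    w[paste0("t", tp, "_control")] <- -1
    attr(w, "timepoint") <- tp
    w
  })
  names(out) <- paste0("t", tps, "_treated_vs_control")
  out
}

# Contrast estimate and its Wald standard error per gene (natural log).
contrast_estimates <- function(fit, contrast) {
  stopifnot(inherits(fit, "nbglm_fit"))
  w <- as.numeric(contrast)
  stopifnot(length(w) == ncol(fit$coefficients), any(w != 0))
  est <- as.numeric(fit$coefficients %*% w)
  G <- dim(fit$cov)[3L]
  se <- vapply(seq_len(G), function(g) {
    v <- as.numeric(crossprod(w, fit$cov[, , g] %*% w))
    sqrt(max(v, 0))
  }, numeric(1))
  degen <- rowSums(fit$zero_cell[, w != 0, drop = FALSE]) > 0
  list(estimate = est, se = se, degenerate = as.logical(degen))
}

# Vector-level primitives ---------------------------------------------------

#' Wald p-value for H0: effect = 0
#'
#' Two-sided normal p-value for `estimate / se`. Degenerate inputs
#' (non-finite or non-positive `se`) give p = 1.
#'
#' @param estimate Effect estimates (natural or log2 scale, consistently
#'   with `se`).
#' @param se Standard errors.
#' @return p-values in \[0, 1\].
#' @export
wald_p_de <- function(estimate, se) {
  bad <- !is.finite(estimate) | !is.finite(se) | se <= 0
  z <- ifelse(bad, 0, estimate / se)
  2 * stats::pnorm(-abs(z))
}

#' Threshold (TREAT-style) Wald p-value for H0: |effect| <= tau
#'
#' Tests against a fold-change cutoff rather than zero: with
#' `t = |estimate| / se` and `taus = tau / se`, the p-value is
#' `P(Z > t - taus) + P(Z > t + taus)`. At `tau = 0` this reduces exactly
#' to [wald_p_de()].
#'
#' @inheritParams wald_p_de
#' @param tau Non-negative threshold on the same scale as `estimate`.
#' @return p-values in \[0, 1\].
#' @export
wald_p_threshold <- function(estimate, se, tau) {
  stopifnot(tau >= 0)
  bad <- !is.finite(estimate) | !is.finite(se) | se <= 0
  t <- ifelse(bad, 0, abs(estimate) / se)
  taus <- ifelse(bad, 0, tau / se)
  p <- stats::pnorm(t - taus, lower.tail = FALSE) +
    stats::pnorm(t + taus, lower.tail = FALSE)
  pmin(p, 1)
}

#' TOST equivalence p-value for H0: |effect| >= tau
#'
#' Two one-sided tests: `p1 = 1 - pnorm((estimate + tau) / se)` and
#' `p2 = pnorm((estimate - tau) / se)`; the TOST p-value is `max(p1, p2)`.
#' A small value supports `|effect| < tau`, i.e. equivalence within the
#' fold-change margin. Degenerate inputs give p = 1 (a gene with an empty
#' cell is never declared equivalent).
#'
#' @inheritParams wald_p_threshold
#' @return p-values in \[0, 1\].
#' @export
tost_p_equivalence <- function(estimate, se, tau) {
  stopifnot(tau > 0)
  bad <- !is.finite(estimate) | !is.finite(se) | se <= 0
  p1 <- stats::pnorm((estimate + tau) / se, lower.tail = FALSE)
  p2 <- stats::pnorm((estimate - tau) / se)
  p <- pmax(p1, p2)
  p[bad] <- 1
  p
}

# Fit-level operations ------------------------------------------------------

#' Per-gene DE, threshold and equivalence tests for one contrast
#'
#' @param fit An `nbglm_fit`.
#' @param contrast Weight vector (e.g. one element of
#'   [treatment_contrasts()]).
#' @param fold_change Fold-change defining the threshold/equivalence margin
#'   (the workflow default is 3, i.e. a natural-log cutoff of log 3).
#' @return For `test_de`, `test_de_threshold`, `test_equivalence`: a
#'   numeric vector of p-values, one per gene.
#' @export
test_de <- function(fit, contrast) {
  ce <- contrast_estimates(fit, contrast)
  p <- wald_p_de(ce$estimate, ce$se)
  p[ce$degenerate] <- 1
  p
}

#' @rdname test_de
#' @export
test_de_threshold <- function(fit, contrast, fold_change = 3) {
  stopifnot(fold_change >= 1)
  ce <- contrast_estimates(fit, contrast)
  p <- wald_p_threshold(ce$estimate, ce$se, tau = log(fold_change))
  p[ce$degenerate] <- 1
  p
}

#' @rdname test_de
#' @export
test_equivalence <- function(fit, contrast, fold_change = 3) {
  stopifnot(fold_change > 1)
  ce <- contrast_estimates(fit, contrast)
  p <- tost_p_equivalence(ce$estimate, ce$se, tau = log(fold_change))
  p[ce$degenerate] <- 1
  p
}

#' All per-timepoint contrast results as a long table
#'
#' Runs the ordinary, threshold and equivalence tests for every treatment
#' contrast of the fitted design and returns one row per gene x timepoint.
#' LFCs and their standard errors are reported in log2.
#'
#' @param fit An `nbglm_fit` with `timepoint_by_condition` design.
#' @param fold_change Fold-change margin (default 3).
#' @return A `contrast_results` data.frame with columns `gene_id`,
#'   `time_min`, `lfc_log2`, `se_log2`, `p_de`, `p_threshold`, `p_equiv`,
#'   `degenerate`.
#' @export
test_contrasts <- function(fit, fold_change = 3) {
  contrasts <- treatment_contrasts(fit$design)
  tau <- log(fold_change)
  rows <- lapply(contrasts, function(w) {
    ce <- contrast_estimates(fit, w)
    p_de <- wald_p_de(ce$estimate, ce$se)
    p_thr <- wald_p_threshold(ce$estimate, ce$se, tau)
    p_eq <- tost_p_equivalence(ce$estimate, ce$se, tau)
    p_de[ce$degenerate] <- 1
    p_thr[ce$degenerate] <- 1
    p_eq[ce$degenerate] <- 1
    data.frame(gene_id = fit$gene_ids,
               time_min = attr(w, "timepoint"),
               lfc_log2 = ce$estimate / log(2),
               se_log2 = ce$se / log(2),
               p_de = p_de, p_threshold = p_thr, p_equiv = p_eq,
               degenerate = ce$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_results", "data.frame")
  attr(out, "fold_change") <- fold_change
  out
}

#' Omnibus likelihood-ratio screen
#'
#' Gene-level screen for any treatment effect at any timepoint: the LRT
#' statistic is the deviance of the reduced (timepoint-only) fit minus the
#' deviance of the full (timepoint-by-condition) fit, referred to a
#' chi-square with df equal to the number of treatment contrasts. Small
#' negative statistics (numerical noise) are clamped to zero; negative
#' statistics beyond -1e-6 indicate a fit failure and raise an error.
#'
#' @param fit_full `nbglm_fit` under the full design.
#' @param fit_reduced `nbglm_fit` under the nested timepoint-only design.
#' @return Vector of per-gene screening p-values with a `df` attribute.
#' @export
screen_omnibus <- function(fit_full, fit_reduced) {
  stopifnot(identical(fit_full$gene_ids, fit_reduced$gene_ids))
  df <- ncol(fit_full$design) - ncol(fit_reduced$design)
  stat <- fit_reduced$deviance - fit_full$deviance
  if (df == 0L) return(structure(rep(1, length(stat)), df = 0L))
  if (any(stat < -1e-6)) {
    stop("negative LRT statistic beyond tolerance for gene(s) ",
         paste(utils::head(fit_full$gene_ids[stat < -1e-6], 5), collapse = ", "),
         "; reduced model does not appear nested in the full model")
  }
  stat <- pmax(stat, 0)
  structure(stats::pchisq(stat, df = df, lower.tail = FALSE), df = df)
}
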