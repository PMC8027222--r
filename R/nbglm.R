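#' Build a cell-means design matrix
#'
#' With `parameterization = "timepoint_by_condition"` (the model used for
#' all per-timepoint tests), one mean parameter is assigned to every
#' (timepoint, condition) cell present in the data; a control-only timepoint
#' (the 0 h dark sample) gets a single parameter. Columns are named
#' `t<minutes>_<condition>`. The time trend shared by control and treated
#' cultures (the dark-to-light response) is absorbed by the per-timepoint
#' means, so treatment contrasts are orthogonal to it.
#' `"timepoint_only"` drops the condition split and is the reduced model of
#' the omnibus screen.
#'
#' @param samples A `sample_table`.
#' @param parameterization `"timepoint_by_condition"` or `"timepoint_only"`.
#' @return A samples x p design matrix with 0/1 entries and an attribute
#'   `cells` (data.frame of column, time_min, condition) plus `timepoints`,
#'   the minutes at which both conditions are present.
#' @export
build_design <- function(samples,
                         parameterization = c("timepoint_by_condition",
                                              "timepoint_only")) {
  parameterization <- match.arg(parameterization)
  if (parameterization == "timepoint_by_condition") {
    cell <- paste0("t", samples$time_min, "_", samples$condition)
  } else {
    cell <- paste0("t", samples$time_min)
  }
  lev <- unique(cell[order(samples$time_min, samples$condition)])
  X <- vapply(lev, function(l) as.numeric(cell == l),
              numeric(length(cell)))
  dimnames(X) <- list(samples$sample_id, lev)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design is rank deficient; aliased column(s): ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  }
  tab <- table(samples$time_min, samples$condition)
  both <- as.numeric(rownames(tab))[rowSums(tab > 0) == 2L]
  cells <- data.frame(column = lev,
                      time_min = samples$time_min[match(lev, cell)],
                      condition = if (parameterization == "timepoint_by_condition")
                        samples$condition[match(lev, cell)] else NA_character_,
                      stringsAsFactors = FALSE)
  attr(X, "cells") <- cells
  attr(X, "timepoints") <- sort(both)
  attr(X, "parameterization") <- parameterization
  X
}

#' Negative binomial GLM fits for all genes
#'
#' Fits, per gene, a negative binomial log-linear model with the given
#' design, offsets and gene-wise dispersions, by maximum likelihood
#' (edgeR's damped Fisher scoring, no fold-change shrinkage). Coefficients
#' are kept on the natural-log scale internally; all user-facing
#' log-fold-changes are reported in log2. Wald standard errors are derived
#' from the observed information `X' W X` with working weights
#' `w = mu / (1 + phi * mu)` evaluated at the optimum.
#'
#' @param bundle An `experiment_bundle` (typically already filtered).
#' @param design Design matrix from [build_design()].
#' @param dispersion Per-gene dispersions (scalar recycled), e.g. the
#'   `tagwise` component of [estimate_dispersions()].
#' @param factors Optional `norm_factors`; offsets are the natural log of
#'   effective library sizes.
#' @return An `nbglm_fit` list: `coefficients` (genes x p, natural log),
#'   `se` (same shape), `cov` (p x p x genes array), `fitted`, `deviance`,
#'   `dispersion`, `design`, `offset` and a logical `zero_cell` matrix
#'   (genes x cells) marking cells with no counts at all, for which the
#'   cell mean lies on the boundary of the parameter space.
#' @export
fit_nbglm <- function(bundle, design, dispersion, factors = NULL) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  counts <- bundle$counts
  if (is.null(factors)) factors <- norm_factors(bundle)
  offset <- log(factors$effective_size)
  G <- nrow(counts); p <- ncol(design)
  dispersion <- rep_len(dispersion, G)
  fit <- edgeR::glmFit(counts, design = design, dispersion = dispersion,
                       offset = offset, prior.count = 0)
  beta <- fit$coefficients            # natural log scale
  mu <- fit$fitted.values
  w <- mu / (1 + dispersion * mu)     # genes x samples working weights
  covs <- array(NA_real_, dim = c(p, p, G),
                dimnames = list(colnames(design), colnames(design), NULL))
  se <- matrix(NA_real_, G, p, dimnames = dimnames(beta))
  for (g in seq_len(G)) {
    info <- crossprod(design, w[g, ] * design)
    V <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(V)) V <- matrix(NA_real_, p, p)
    covs[, , g] <- V
    se[g, ] <- sqrt(pmax(diag(V), 0))
  }
  zero_cell <- (counts %*% design) == 0
  structure(list(gene_ids = rownames(counts),
                 coefficients = beta, se = se, cov = covs,
                 fitted = mu, deviance = unname(fit$deviance),
                 dispersion = dispersion, design = design, offset = offset,
                 zero_cell = zero_cell),
            class = "nbglm_fit")
}

#' Fit one gene
#'
#' Single-gene convenience wrapper around [fit_nbglm()] for a raw count
#' vector, a design matrix and a known dispersion; offsets default to zero
#' (so fitted means are on the count scale).
#'
#' @param counts_g Integer vector of per-sample counts.
#' @param design Design matrix (full column rank).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param offset Per-sample offsets on the natural-log scale.
#' @return An `nbglm_fit` with a single gene.
#' @export
fit_gene <- function(counts_g, design, dispersion, offset = rep(0, length(counts_g))) {
  n <- length(counts_g)
  stopifnot(nrow(design) == n, length(offset) == n)
  counts <- matrix(as.numeric(counts_g), nrow = 1,
                   dimnames = list("gene", rownames(design)))
  fit <- edgeR::glmFit(counts, design = design, dispersion = dispersion,
                       offset = offset, prior.count = 0)
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- as.numeric(mu) / (1 + dispersion * as.numeric(mu))
  info <- crossprod(design, w * design)
  V <- chol2inv(chol(info))
  p <- ncol(design)
  structure(list(gene_ids = "gene",
                 coefficients = beta,
                 se = matrix(sqrt(pmax(diag(V), 0)), 1, p,
                             dimnames = dimnames(beta)),
                 cov = array(V, dim = c(p, p, 1),
                             dimnames = list(colnames(design),
                                             colnames(design), NULL)),
                 fitted = mu, deviance = unname(fit$deviance),
                 dispersion = dispersion, design = design, offset = offset,
                 zero_cell = (counts %*% design) == 0),
            class = "nbglm_fit")
}

#' Negative binomial deviance
#'
#' Residual deviance `2 * sum(y * log(y / mu) - (y + 1/phi) *
#' log((1 + phi y) / (1 + phi mu)))` with the `y log(y/mu)` term taken as 0
#' at `y = 0`; reduces to the Poisson deviance as `phi -> 0`.
#'
#' @param y Observed counts.
#' @param mu Fitted means (positive).
#' @param dispersion NB dispersion phi; `0` gives the Poisson deviance.
#' @return Non-negative deviance (summed over samples).
#' @export
nb_deviance <- function(y, mu, dispersion) {
  stopifnot(all(mu > 0), length(y) == length(mu))
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (dispersion <= 0) {
    d <- 2 * sum(t1 - (y - mu))
  } else {
    t2 <- (y + 1 / dispersion) * log((1 + dispersion * y) / (1 + dispersion * mu))
    d <- 2 * sum(t1 - t2)
  }
  max(d, 0)
}

#' Empirical Bayes dispersion estimation
#'
#' Gene-wise NB dispersions via Cox-Reid adjusted profile likelihood, a
#' trend on average log-CPM, and weighted-likelihood shrinkage of the
#' gene-wise estimates toward the trend with `prior_df` prior degrees of
#' freedom (edgeR's `estimateDisp`). With very large `prior_df` the tagwise
#' values coincide with the trend.
#'
#' @param bundle An `experiment_bundle`.
#' @param design Design matrix.
#' @param factors Optional `norm_factors`.
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @return A `dispersion_estimates` list: `common`, `trended`, `tagwise`,
#'   `prior_df`, `ave_logcpm`.
#' @export
estimate_dispersions <- function(bundle, design, factors = NULL, prior_df = 10) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (is.null(factors)) factors <- norm_factors(bundle)
  if (ncol(bundle$counts) <= ncol(design)) {
    stop("no residual degrees of freedom to estimate dispersions; ",
         "supply a dispersion directly to fit_nbglm()")
  }
  d <- edgeR::DGEList(counts = bundle$counts,
                      lib.size = factors$library_size,
                      norm.factors = factors$tmm_factor)
  d <- edgeR::estimateDisp(d, design = design, prior.df = prior_df)
  structure(list(common = d$common.dispersion,
                 trended = d$trended.dispersion,
                 tagwise = d$tagwise.dispersion,
                 prior_df = prior_df,
                 ave_logcpm = d$AveLogCPM),
            class = "dispersion_estimates")
}

#' @export
print.nbglm_fit <- function(x, ...) {
  cat("nbglm_fit:", length(x$gene_ids), "genes,",
      ncol(x$coefficients), "coefficients\n")
  invisible(x)
}
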