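#' Leading log-fold-change distance between samples
#'
#' For every pair of samples, the root-mean-square of the `top_n` largest
#' absolute log2-CPM differences between them (gene selection is pairwise,
#' so each pair uses its own top genes). This is the distance whose MDS
#' embedding "approximates the log2 fold changes of the top genes" between
#' samples.
#'
#' @param logcpm genes x samples matrix of log2-CPM values.
#' @param top_n Number of top genes per pair (default 500); when the
#'   matrix has fewer genes, all are used.
#' @return Symmetric samples x samples distance matrix with zero diagonal.
#' @export
leading_logfc_distance <- function(logcpm, top_n = 500) {
  n <- ncol(logcpm)
  top_n <- min(top_n, nrow(logcpm))
  d <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dif <- (logcpm[, i] - logcpm[, j])^2
      top <- sort(dif, decreasing = TRUE)[seq_len(top_n)]
      d[i, j] <- d[j, i] <- sqrt(mean(top))
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Eigendecomposition of the double-centered squared distance matrix;
#' coordinates are the top-k eigenvectors scaled by the square roots of
#' their eigenvalues. For a sign convention, each axis is flipped so that
#' its first nonzero loading is positive. If fewer than `k` positive
#' eigenvalues exist, the embedding is truncated with a warning.
#'
#' @param dist Symmetric distance matrix with zero diagonal.
#' @param k Target dimension (default 2).
#' @return An `mds_embedding` list: `points` (samples x k, rownames kept),
#'   `eigenvalues` (all, non-increasing), `k`.
#' @export
classical_mds <- function(dist, k = 2) {
  dist <- as.matrix(dist)
  stopifnot(nrow(dist) == ncol(dist))
  if (max(abs(dist - t(dist))) > 1e-8 || any(abs(diag(dist)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  n <- nrow(dist)
  fit <- stats::cmdscale(dist, k = min(k, n - 1L), eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1))
  keff <- min(k, npos)
  if (keff < k) {
    warning("only ", npos, " positive eigenvalue(s); embedding truncated to ",
            keff, " dimension(s)")
  }
  pts <- fit$points[, seq_len(keff), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) > 0L && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(dist)
  structure(list(points = pts, eigenvalues = eig, k = keff),
            class = "mds_embedding")
}

#' Z-score genes within sample groups
#'
#' Standardizes each gene to zero mean and unit variance separately within
#' each group of samples (e.g. per mating type), the transform used for
#' cross-dataset expression heatmaps. Rows with zero variance in a group
#' are set to 0 there and flagged.
#'
#' @param mat genes x samples matrix (e.g. CPM).
#' @param groups Character/factor vector of length `ncol(mat)`.
#' @return Matrix of the same shape with a logical `constant` attribute
#'   (genes x groups) marking zero-variance rows.
#' @export
zscore_by_group <- function(mat, groups) {
  stopifnot(length(groups) == ncol(mat))
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  out <- mat
  const <- matrix(FALSE, nrow(mat), nlevels(groups),
                  dimnames = list(rownames(mat), levels(groups)))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- mat[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    zero <- sdv == 0 | !is.finite(sdv)
    sdv[zero] <- 1
    out[, idx] <- (sub - mu) / sdv
    out[zero, idx] <- 0
    const[, g] <- zero
  }
  attr(out, "constant") <- const
  out
}

#' CPM trajectories for selected genes
#'
#' Long-format table of per-replicate CPM and per-cell mean CPM as a
#' function of time and condition, the data behind expression-over-time
#' panels.
#'
#' @param cpm genes x samples CPM matrix.
#' @param samples Matching `sample_table`.
#' @param genes Gene ids to extract.
#' @return data.frame with columns `gene_id`, `time_min`, `timepoint`,
#'   `condition`, `replicate`, `cpm`, `mean_cpm` (cell mean repeated per
#'   replicate).
#' @export
cpm_trajectories <- function(cpm, samples, genes) {
  missing_genes <- setdiff(genes, rownames(cpm))
  if (length(missing_genes) > 0L) {
    stop("unknown gene(s): ", paste(missing_genes, collapse = ", "))
  }
  stopifnot(identical(colnames(cpm), samples$sample_id))
  rows <- lapply(genes, function(g) {
    df <- data.frame(gene_id = g,
                     time_min = samples$time_min,
                     timepoint = as.character(samples$timepoint),
                     condition = samples$condition,
                     replicate = samples$replicate,
                     cpm = as.numeric(cpm[g, ]),
                     stringsAsFactors = FALSE)
    means <- stats::aggregate(cpm ~ time_min + condition, data = df, FUN = mean)
    df$mean_cpm <- means$cpm[match(paste(df$time_min, df$condition),
                                   paste(means$time_min, means$condition))]
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$time_min, out$condition, out$replicate), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
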