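#' Simulation configuration
#'
#' Defines the synthetic two-mating-type experiment the package is
#' calibrated against: an MT+ time course with a control-only dark sample
#' (0 h) plus five post-illumination timepoints with control and treated
#' replicates, and an MT- side composed of two experiments (15 min/1 h/3 h
#' and 10 h). Counts are negative binomial with gene-wise dispersions, a
#' per-gene dark-to-light time trend shared by the two conditions, and
#' planted gene classes: SRB (responsive in both datasets), SRP (MT+
#' only), SRM (MT- only), one filtered class per side (essentially
#' unexpressed in the designated dataset), and null genes with true
#' |log2 LFC| below `null_lfc_max_log2`, i.e. genuinely equivalent within
#' the fold-change margin.
#'
#' Responder log2-LFC magnitudes are drawn uniformly from
#' `lfc_range_log2`, with MT- magnitudes `minus_scale` times larger
#' (the MT- response being the more pronounced one). Responder baselines
#' are drawn from a truncated lognormal so that key genes are moderately
#' to highly expressed; background baselines span a wider lognormal.
#' Dispersions follow `phi = disp_b + disp_a / mu` with lognormal
#' gene-wise jitter.
#'
#' @param n_genes Total genes (default 10000).
#' @param reps Replicates per (timepoint, condition) cell (default 3).
#' @param timepoints_plus MT+ timepoints in minutes; the first is the
#'   control-only dark sample.
#' @param timepoints_minus_a,timepoints_minus_b MT- timepoints of the two
#'   experiments (batches A and B).
#' @param n_srb,n_srp,n_srm,n_filtered_plus,n_filtered_minus Planted class
#'   sizes; the remainder is null.
#' @param lfc_range_log2 Range of responder |log2 LFC| (default
#'   `[log2(3) + 0.5, 4]`, above the fold-change-3 cutoff).
#' @param null_lfc_max_log2 Maximum |log2 LFC| of null genes (default
#'   0.2).
#' @param minus_scale Multiplier on MT- responder magnitudes (default
#'   1.25).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of
#'   background baseline expected counts (at a 1e6 library).
#' @param responder_meanlog,responder_sdlog,responder_min Truncated
#'   lognormal parameters of responder baselines.
#' @param filtered_baseline Expected count of filtered-class genes in the
#'   dataset where they are unexpressed (default 0.01).
#' @param disp_a,disp_b,disp_jitter_sd Dispersion trend `disp_b +
#'   disp_a/mu` and lognormal jitter sd.
#' @param lib_size_range Uniform range of library sizes (default 0.5e6 to
#'   2e6).
#' @param trend_sd Sd of the per-gene log-scale dark-to-light trend
#'   coefficient (default 1); 0 switches the trend off.
#' @param seed Integer seed; every random draw flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 10000, reps = 3,
                       timepoints_plus = c(0, 15, 60, 180, 360, 540),
                       timepoints_minus_a = c(15, 60, 180),
                       timepoints_minus_b = 600,
                       n_srb = 200, n_srp = 100, n_srm = 100,
                       n_filtered_plus = 100, n_filtered_minus = 100,
                       lfc_range_log2 = c(log2(3) + 0.5, 4),
                       null_lfc_max_log2 = 0.2,
                       minus_scale = 1.25,
                       baseline_meanlog = log(50), baseline_sdlog = 1.5,
                       responder_meanlog = log(200), responder_sdlog = 1,
                       responder_min = 50,
                       filtered_baseline = 0.01,
                       disp_a = 1.5, disp_b = 0.04, disp_jitter_sd = 0.25,
                       lib_size_range = c(0.5e6, 2e6),
                       trend_sd = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  n_classes <- n_srb + n_srp + n_srm + n_filtered_plus + n_filtered_minus
  if (n_classes > n_genes) stop("planted class counts exceed n_genes")
  if (lfc_range_log2[1] <= log2(3)) {
    stop("responder LFC range must lie above the log2(3) cutoff")
  }
  if (null_lfc_max_log2 >= log2(3)) {
    stop("null LFC bound must lie below the log2(3) cutoff")
  }
  stopifnot(reps >= 2, diff(lfc_range_log2) >= 0,
            diff(lib_size_range) >= 0, lib_size_range[1] > 0)
  class(cfg) <- "sim_config"
  cfg
}

# Sample layout of one dataset.
sim_layout <- function(dataset, mating_type, timepoints, reps, batch,
                       control_only = numeric(0)) {
  rows <- lapply(timepoints, function(tp) {
    conds <- if (tp %in% control_only) "control" else c("control", "treated")
    expand.grid(time_min = tp, condition = conds, replicate = seq_len(reps),
                stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$time_min, df$condition, df$replicate), , drop = FALSE]
  df$dataset <- dataset
  df$mating_type <- mating_type
  df$experiment_batch <- batch[match(df$time_min, as.numeric(names(batch)))]
  df$timepoint <- ifelse(df$time_min %% 60 == 0, paste0(df$time_min / 60, "h"),
                         paste0(df$time_min, "min"))
  df$sample_id <- paste0(dataset, "_t", df$time_min, "_",
                         df$condition, "_r", df$replicate)
  df[, c("sample_id", "dataset", "mating_type", "timepoint", "condition",
         "replicate", "experiment_batch", "time_min")]
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  pl <- stats::plnorm(lower, meanlog, sdlog)
  stats::qlnorm(pl + stats::runif(n) * (1 - pl), meanlog, sdlog)
}

#' Simulate the two-dataset experiment
#'
#' Draws both datasets and the ground truth from a [sim_config()]. Counts
#' for gene g in sample i are NB with mean
#' `baseline_g * trend_g(t_i) * exp(lfc) * lib_i / 1e6` and dispersion
#' `phi_g`, where the trend multiplier is `exp(b_g * s(t))` with a
#' saturating ramp `s(t) = t / (t + 60)` scaled to \[0, 1\] over the
#' design, identical for control and treated samples. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return List with `plus` and `minus` (`experiment_bundle`s) and
#'   `truth`, a `truth_table`: `genes` (data.frame of `gene_id`, `class`,
#'   baselines, `dispersion`, `trend_coef`) plus true log2-LFC matrices
#'   `lfc_plus` and `lfc_minus` (genes x treated timepoints).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(G))
  classes <- rep("null", G)
  idx <- 0L
  for (cl in c("SRB", "SRP", "SRM", "filtered_plus", "filtered_minus")) {
    n_cl <- switch(cl, SRB = cfg$n_srb, SRP = cfg$n_srp, SRM = cfg$n_srm,
                   filtered_plus = cfg$n_filtered_plus,
                   filtered_minus = cfg$n_filtered_minus)
    if (n_cl > 0L) classes[idx + seq_len(n_cl)] <- cl
    idx <- idx + n_cl
  }
  responder <- classes %in% c("SRB", "SRP", "SRM")

  baseline <- stats::rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
  baseline[responder] <- rlnorm_trunc(sum(responder), cfg$responder_meanlog,
                                      cfg$responder_sdlog, cfg$responder_min)
  baseline_plus <- baseline
  baseline_minus <- baseline
  baseline_plus[classes == "filtered_plus"] <- cfg$filtered_baseline
  baseline_minus[classes == "filtered_minus"] <- cfg$filtered_baseline

  phi <- (cfg$disp_b + cfg$disp_a / pmax(baseline, 1)) *
    stats::rlnorm(G, 0, cfg$disp_jitter_sd)
  trend_coef <- stats::rnorm(G, 0, cfg$trend_sd)

  mag <- stats::runif(G, cfg$lfc_range_log2[1], cfg$lfc_range_log2[2])
  sgn <- ifelse(stats::runif(G) < 0.5, -1, 1)
  small_plus <- stats::runif(G, -cfg$null_lfc_max_log2, cfg$null_lfc_max_log2)
  small_minus <- stats::runif(G, -cfg$null_lfc_max_log2, cfg$null_lfc_max_log2)

  lfc1_plus <- small_plus
  lfc1_minus <- small_minus
  in_plus <- classes %in% c("SRB", "SRP")
  in_minus <- classes %in% c("SRB", "SRM")
  lfc1_plus[in_plus] <- (sgn * mag)[in_plus]
  lfc1_minus[in_minus] <- (sgn * mag * cfg$minus_scale)[in_minus]

  samples_plus <- sample_table(sim_layout(
    "MTplus", "MTplus", cfg$timepoints_plus, cfg$reps,
    batch = stats::setNames(rep("P", length(cfg$timepoints_plus)),
                            cfg$timepoints_plus),
    control_only = cfg$timepoints_plus[1]))
  tp_minus <- c(cfg$timepoints_minus_a, cfg$timepoints_minus_b)
  samples_minus <- sample_table(sim_layout(
    "MTminus", "MTminus", tp_minus, cfg$reps,
    batch = stats::setNames(c(rep("A", length(cfg$timepoints_minus_a)),
                              rep("B", length(cfg$timepoints_minus_b))),
                            tp_minus)))

  treated_tp_plus <- setdiff(cfg$timepoints_plus, cfg$timepoints_plus[1])
  lfc_plus <- matrix(lfc1_plus, G, length(treated_tp_plus),
                     dimnames = list(gene_ids, treated_tp_plus))
  lfc_minus <- matrix(lfc1_minus, G, length(tp_minus),
                      dimnames = list(gene_ids, tp_minus))

  t_max <- max(cfg$timepoints_plus, tp_minus)
  ramp <- function(t) if (t_max == 0) 0 else (t / (t + 60)) / (t_max / (t_max + 60))

  draw_counts <- function(samples, base, lfc_mat) {
    n <- nrow(samples)
    libs <- stats::runif(n, cfg$lib_size_range[1], cfg$lib_size_range[2])
    mu <- matrix(0, G, n)
    for (i in seq_len(n)) {
      tp <- samples$time_min[i]
      lfc <- if (samples$condition[i] == "treated") {
        lfc_mat[, as.character(tp)]
      } else 0
      mu[, i] <- base * exp(trend_coef * ramp(tp)) * 2^lfc * libs[i] / 1e6
    }
    y <- stats::rnbinom(G * n, size = rep(1 / phi, n), mu = as.vector(mu))
    counts <- matrix(as.numeric(y), G, n,
                     dimnames = list(gene_ids, samples$sample_id))
    counts
  }
  counts_plus <- draw_counts(samples_plus, baseline_plus, lfc_plus)
  counts_minus <- draw_counts(samples_minus, baseline_minus, lfc_minus)

  truth <- structure(list(
    genes = data.frame(gene_id = gene_ids, class = classes,
                       baseline_plus = baseline_plus,
                       baseline_minus = baseline_minus,
                       dispersion = phi, trend_coef = trend_coef,
                       stringsAsFactors = FALSE),
    lfc_plus = lfc_plus, lfc_minus = lfc_minus), class = "truth_table")

  list(plus = bundle(counts_plus, samples_plus),
       minus = bundle(counts_minus, samples_minus),
       truth = truth)
}

#' Write a simulated experiment to ingest-compatible files
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"mtx"` for the count matrices.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (side in c("plus", "minus")) {
    b <- sim[[side]]
    ext <- if (format == "tsv") ".tsv" else ".mtx"
    if (format == "mtx") {
      sub <- file.path(dir, paste0("counts_", side))
      dir.create(sub, showWarnings = FALSE)
      write_counts(b$counts, file.path(sub, paste0("counts", ext)), format)
    } else {
      write_counts(b$counts, file.path(dir, paste0("counts_", side, ext)), format)
    }
    write_samples(b$samples, file.path(dir, paste0("samples_", side, ".tsv")))
  }
  tg <- sim$truth$genes
  for (side in c("plus", "minus")) {
    m <- sim$truth[[paste0("lfc_", side)]]
    colnames(m) <- paste0("lfc_", side, "_t", colnames(m))
    tg <- cbind(tg, m)
  }
  utils::write.table(tg, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score a classification against simulator truth
#'
#' Per-class precision and recall for SRB/SRP/SRM, the confusion matrix,
#' and the false discovery proportion among discovered key genes (claimed
#' SRB/SRP/SRM whose truth is null), 0 when nothing was discovered.
#'
#' @param cls A `gene_classification`.
#' @param truth A `truth_table`.
#' @return List with `confusion` (truth x claimed table), `per_class`
#'   (data.frame of class, n_true, n_claimed, precision, recall) and
#'   `fdp`.
#' @export
evaluate_classification <- function(cls, truth) {
  tg <- truth$genes
  if (!all(cls$gene_id %in% tg$gene_id)) {
    stop("classification contains gene ids absent from the truth table")
  }
  claimed <- stats::setNames(cls$class, cls$gene_id)[tg$gene_id]
  claimed[is.na(claimed)] <- "unclassified"
  truth_cls <- tg$class
  confusion <- table(truth = truth_cls, claimed = claimed)
  key <- c("SRB", "SRP", "SRM")
  per_class <- do.call(rbind, lapply(key, function(cl) {
    n_true <- sum(truth_cls == cl)
    n_claimed <- sum(claimed == cl)
    tp <- sum(truth_cls == cl & claimed == cl)
    data.frame(class = cl, n_true = n_true, n_claimed = n_claimed,
               precision = if (n_claimed > 0) tp / n_claimed else NA_real_,
               recall = if (n_true > 0) tp / n_true else NA_real_,
               stringsAsFactors = FALSE)
  }))
  n_disc <- sum(claimed %in% key)
  fdp <- if (n_disc > 0) sum(claimed %in% key & truth_cls == "null") / n_disc else 0
  list(confusion = confusion, per_class = per_class, fdp = fdp,
       empty_discovery = n_disc == 0)
}

# True per-dataset responder status at the fold-change cutoff: does the
# gene exceed the threshold at any timepoint of that dataset?
true_responders <- function(truth, side, fold_change = 3) {
  m <- truth[[paste0("lfc_", side)]]
  apply(abs(m) > log2(fold_change), 1, any)
}

#' Replicated OFDR / power experiment
#'
#' Runs the full per-dataset stage-wise pipeline on `n_reps` fresh
#' simulations (seeds `cfg$seed + 0 .. n_reps - 1`) and summarizes the
#' gene-level overall FDR (falsely rejected genes over rejected genes,
#' where a rejection is any confirmed per-timepoint threshold call and a
#' false rejection is one for a gene with no true above-threshold LFC in
#' that dataset), the key-gene classification FDP, and per-class recovery,
#' with Monte-Carlo standard errors.
#'
#' @param cfg A `sim_config`; its seed anchors the replicate seeds.
#' @param n_reps Number of replicates (>= 2).
#' @param alpha Target OFDR level (default 0.05).
#' @param fold_change Fold-change margin (default 3).
#' @return List with `summary` (data.frame of metric, mean, se) and
#'   `per_rep` (one row per replicate and dataset).
#' @export
run_ofdr_experiment <- function(cfg, n_reps = 25, alpha = 0.05,
                                fold_change = 3) {
  stopifnot(n_reps >= 2)
  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    sim <- simulate_experiment(cfg_r)
    res <- run_sip_pipeline(sim$plus, sim$minus, fold_change = fold_change,
                            alpha = alpha)
    rows <- lapply(c("plus", "minus"), function(side) {
      dec <- res[[side]]$decisions
      rejected <- rownames(dec$de_confirmed)[rowSums(dec$de_confirmed) > 0]
      truth_resp <- true_responders(sim$truth, side, fold_change)
      n_rej <- length(rejected)
      n_false <- sum(!truth_resp[rejected])
      data.frame(rep = r, dataset = side, n_rejected = n_rej,
                 n_false = n_false,
                 ofdr = if (n_rej > 0) n_false / n_rej else 0,
                 stringsAsFactors = FALSE)
    })
    ev <- evaluate_classification(res$classification, sim$truth)
    rec <- stats::setNames(ev$per_class$recall, ev$per_class$class)
    prec <- stats::setNames(ev$per_class$precision, ev$per_class$class)
    info <- do.call(rbind, rows)
    info$key_fdp <- ev$fdp
    for (cl in c("SRB", "SRP", "SRM")) {
      info[[paste0("recall_", cl)]] <- rec[[cl]]
      info[[paste0("precision_", cl)]] <- prec[[cl]]
    }
    per_rep[[r]] <- info
  }
  per_rep <- do.call(rbind, per_rep)
  mc <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  by_rep_ofdr <- tapply(per_rep$ofdr, per_rep$rep, mean)  # dataset-averaged
  metrics <- rbind(
    data.frame(metric = "ofdr", t(mc(as.numeric(by_rep_ofdr)))),
    data.frame(metric = "ofdr_plus", t(mc(per_rep$ofdr[per_rep$dataset == "plus"]))),
    data.frame(metric = "ofdr_minus", t(mc(per_rep$ofdr[per_rep$dataset == "minus"]))),
    data.frame(metric = "key_fdp",
               t(mc(per_rep$key_fdp[per_rep$dataset == "plus"]))))
  for (cl in c("SRB", "SRP", "SRM")) {
    sel <- per_rep$dataset == "plus"
    metrics <- rbind(metrics,
      data.frame(metric = paste0("recall_", cl),
                 t(mc(per_rep[[paste0("recall_", cl)]][sel]))),
      data.frame(metric = paste0("precision_", cl),
                 t(mc(per_rep[[paste0("precision_", cl)]][sel]))))
  }
  rownames(metrics) <- NULL
  list(summary = metrics, per_rep = per_rep, alpha = alpha)
}
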