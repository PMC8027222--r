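# Shared fixtures, all generated in code.

# Tiny deterministic bundle: one timepoint, control vs treated, r reps each.
make_two_group_bundle <- function(counts, reps = NULL, dataset = "toy") {
  if (is.null(reps)) reps <- ncol(counts) / 2
  n <- ncol(counts)
  stopifnot(n == 2 * reps)
  samples <- data.frame(
    sample_id = colnames(counts),
    dataset = dataset, mating_type = "MTplus", timepoint = "1h",
    condition = rep(c("control", "treated"), each = reps),
    replicate = rep(seq_len(reps), 2))
  bundle(counts, sample_table(samples))
}

# Null NB bundle (no treatment effect): G genes, one timepoint, 3v3.
make_null_bundle <- function(G = 500, reps = 3, mu = 100, phi = 0.1,
                             seed = 1) {
  set.seed(seed)
  counts <- matrix(rnbinom(G * 2 * reps, mu = mu, size = 1 / phi),
                   G, 2 * reps,
                   dimnames = list(sprintf("g%04d", 1:G),
                                   paste0("s", seq_len(2 * reps))))
  make_two_group_bundle(counts, reps)
}

# Small simulation config for fast end-to-end tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_genes = 2000, n_srb = 40, n_srp = 20, n_srm = 20,
             n_filtered_plus = 20, n_filtered_minus = 20, seed = seed, ...)
}

# Decision table crafted from target calls (via the real stage-wise path):
# de / equiv are logical genes x timepoints matrices.
make_decision_table <- function(gene_ids, timepoints, de, equiv,
                                alpha = 0.05) {
  G <- length(gene_ids)
  T <- length(timepoints)
  screened <- rowSums(de) > 0
  p_screen <- ifelse(screened, 1e-12, 1)
  names(p_screen) <- gene_ids
  p_confirm <- matrix(ifelse(de, 1e-12, 1), G, T,
                      dimnames = list(gene_ids, timepoints))
  p_equiv <- matrix(ifelse(equiv, 1e-12, 1), G, T,
                    dimnames = list(gene_ids, timepoints))
  stagewise_decisions(p_screen, p_confirm, p_equiv, alpha = alpha)
}

make_filter_result <- function(kept, filtered = character(0)) {
  structure(list(kept = kept, filtered = filtered,
                 rule_params = list(cpm_threshold = 1, min_samples = 3)),
            class = "filter_result")
}
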