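test_that("simulation is deterministic in the seed", {
  s1 <- simulate_experiment(small_sim_config(seed = 3))
  s2 <- simulate_experiment(small_sim_config(seed = 3))
  expect_identical(s1$plus$counts, s2$plus$counts)
  expect_identical(s1$minus$counts, s2$minus$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(small_sim_config(seed = 4))
  expect_false(identical(s1$plus$counts, s3$plus$counts))
})

test_that("the layouts match the two mating-type designs", {
  sim <- simulate_experiment(small_sim_config())
  sp <- sim$plus$samples
  expect_equal(ncol(sim$plus$counts), 33)  # 3 + 5 x 2 x 3
  expect_equal(ncol(sim$minus$counts), 24)  # (3 + 1) x 2 x 3
  expect_equal(sum(sp$time_min == 0 & sp$condition == "treated"), 0)
  sm <- sim$minus$samples
  expect_setequal(unique(sm$experiment_batch[sm$time_min == 600]), "B")
  expect_setequal(unique(sm$experiment_batch[sm$time_min < 600]), "A")
  cfg2 <- small_sim_config(reps = 2)
  sim2 <- simulate_experiment(cfg2)
  expect_equal(max(sim2$plus$samples$replicate), 2)
})

test_that("null counts match NB moments when the trend is off", {
  cfg <- sim_config(n_genes = 5000, n_srb = 0, n_srp = 0, n_srm = 0,
                    n_filtered_plus = 0, n_filtered_minus = 0,
                    null_lfc_max_log2 = 0, trend_sd = 0,
                    lib_size_range = c(1e6, 1e6), seed = 2)
  sim <- simulate_experiment(cfg)
  tg <- sim$truth$genes
  y <- sim$plus$counts
  mu_hat <- rowMeans(y)
  # pooled relative error of the mean across genes
  expect_lt(median(abs(mu_hat - tg$baseline_plus) /
                     (tg$baseline_plus + 1)), 0.2)
  # dispersion consistency: regress (var - mu) / mu^2 against truth for
  # well-expressed genes
  v_hat <- apply(y, 1, var)
  expressed <- tg$baseline_plus > 50
  phi_hat <- (v_hat[expressed] - mu_hat[expressed]) / mu_hat[expressed]^2
  expect_equal(median(phi_hat), median(tg$dispersion[expressed]),
               tolerance = 0.3)
})

test_that("planted classes respect the LFC constraints", {
  sim <- simulate_experiment(small_sim_config())
  tg <- sim$truth$genes
  lp <- sim$truth$lfc_plus
  lm_ <- sim$truth$lfc_minus
  shared <- c("15", "60", "180")
  srp <- tg$class == "SRP"
  expect_true(all(abs(lp[srp, shared]) > log2(3)))
  expect_true(all(abs(lm_[srp, shared]) < 0.2))
  srm <- tg$class == "SRM"
  expect_true(all(abs(lm_[srm, shared]) > log2(3)))
  expect_true(all(abs(lp[srm, shared]) < 0.2))
  srb <- tg$class == "SRB"
  expect_true(all(abs(lp[srb, ]) > log2(3)))
  expect_true(all(abs(lm_[srb, ]) > log2(3)))
  # MT- responses are scaled up relative to MT+
  expect_equal(abs(lm_[srb, "15"]) / abs(lp[srb, "15"]),
               rep(1.25, sum(srb)), ignore_attr = TRUE)
  null <- tg$class == "null"
  expect_true(all(abs(lp[null, ]) < log2(3)))
  expect_error(sim_config(n_genes = 100, n_srb = 200), "exceed")
  expect_error(sim_config(lfc_range_log2 = c(1, 4)), "above")
})

test_that("classification metrics match a hand-computed confusion", {
  truth <- structure(list(genes = data.frame(
    gene_id = paste0("g", 1:10),
    class = c("SRB", "SRB", "SRP", "SRP", "SRM", "null", "null", "null",
              "filtered_plus", "filtered_minus"),
    stringsAsFactors = FALSE)), class = "truth_table")
  cls <- data.frame(gene_id = paste0("g", 1:10),
                    class = c("SRB", "SRP", "SRP", "unclassified", "SRM",
                              "SRB", "nonresponsive", "nonresponsive",
                              "nonresponsive", "nonresponsive"),
                    stringsAsFactors = FALSE)
  class(cls) <- c("gene_classification", "data.frame")
  ev <- evaluate_classification(cls, truth)
  pc <- ev$per_class
  expect_equal(pc$precision[pc$class == "SRB"], 1 / 2)  # g1 right, g6 null
  expect_equal(pc$recall[pc$class == "SRB"], 1 / 2)
  expect_equal(pc$precision[pc$class == "SRP"], 1 / 2)  # g3 right, g2 is SRB
  expect_equal(pc$recall[pc$class == "SRP"], 1 / 2)
  expect_equal(pc$precision[pc$class == "SRM"], 1)
  expect_equal(ev$fdp, 1 / 5)  # g6 among 5 claimed key genes
  # perfect classification
  cls2 <- cls
  cls2$class <- truth$genes$class
  cls2$class[!cls2$class %in% c("SRB", "SRP", "SRM")] <- "nonresponsive"
  ev2 <- evaluate_classification(cls2, truth)
  expect_true(all(ev2$per_class$precision == 1, ev2$per_class$recall == 1))
  expect_equal(ev2$fdp, 0)
  # empty discovery set
  cls3 <- cls
  cls3$class <- "nonresponsive"
  ev3 <- evaluate_classification(cls3, truth)
  expect_equal(ev3$fdp, 0)
  expect_true(ev3$empty_discovery)
})

test_that("stronger planted effects never reduce class recovery", {
  cfg_lo <- small_sim_config(seed = 5,
                             lfc_range_log2 = c(log2(3) + 0.3, log2(3) + 0.8))
  cfg_hi <- small_sim_config(seed = 5, lfc_range_log2 = c(3.5, 4.5))
  rec <- function(cfg) {
    sim <- simulate_experiment(cfg)
    res <- run_sip_pipeline(sim$plus, sim$minus)
    ev <- evaluate_classification(res$classification, sim$truth)
    setNames(ev$per_class$recall, ev$per_class$class)
  }
  r_lo <- rec(cfg_lo)
  r_hi <- rec(cfg_hi)
  expect_true(all(r_hi >= r_lo))
})
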