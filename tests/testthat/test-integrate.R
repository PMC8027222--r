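shared3 <- c(15, 60, 180)

# convenience constructors over the helper
dec_from <- function(gene_ids, de_tp = list(), equiv_genes = character(0)) {
  G <- length(gene_ids)
  de <- matrix(FALSE, G, 3, dimnames = list(gene_ids, shared3))
  for (g in names(de_tp)) de[g, as.character(de_tp[[g]])] <- TRUE
  eq <- matrix(FALSE, G, 3, dimnames = list(gene_ids, shared3))
  eq[equiv_genes, ] <- TRUE
  make_decision_table(gene_ids, shared3, de, eq)
}

test_that("shared timepoints follow the two mating-type layouts", {
  sim <- simulate_experiment(small_sim_config())
  expect_equal(shared_timepoints(sim$plus$samples, sim$minus$samples),
               c(15, 60, 180))
  expect_equal(shared_timepoints(sim$plus$samples, sim$plus$samples),
               c(15, 60, 180, 360, 540))
  disjoint <- sim$minus$samples[sim$minus$samples$time_min == 600, ]
  expect_error(shared_timepoints(sim$plus$samples, disjoint),
               "share no timepoint")
})

test_that("classification rules reproduce the workflow's case analysis", {
  ids <- paste0("g", 1:6)
  # g1: DE both -> SRB; g2: DE plus, equivalent minus -> SRP
  # g3: DE minus, filtered plus -> SRM (diamond case)
  # g4: equivalent both -> nonresponsive; g5: DE plus, inconclusive minus
  # g6: equivalent plus, filtered minus -> nonresponsive
  dplus <- dec_from(setdiff(ids, "g3"),
                    de_tp = list(g1 = 60, g2 = 60, g5 = 180),
                    equiv_genes = c("g4", "g6"))
  dminus <- dec_from(setdiff(ids, "g6"),
                     de_tp = list(g1 = 180, g3 = 15),
                     equiv_genes = c("g2", "g4"))
  fplus <- make_filter_result(setdiff(ids, "g3"), "g3")
  fminus <- make_filter_result(setdiff(ids, "g6"), "g6")
  cls <- classify_genes(dplus, dminus, fplus, fminus, shared3)
  got <- setNames(cls$class, cls$gene_id)
  expect_equal(got[["g1"]], "SRB")
  expect_equal(got[["g2"]], "SRP")
  expect_equal(got[["g3"]], "SRM")
  expect_equal(got[["g4"]], "nonresponsive")
  expect_equal(got[["g5"]], "unclassified")
  expect_equal(got[["g6"]], "nonresponsive")
  status <- setNames(cls$other_side_status, cls$gene_id)
  expect_equal(status[["g2"]], "equivalent")
  expect_equal(status[["g3"]], "filtered")
  disc <- setNames(cls$discovery_timepoint, cls$gene_id)
  expect_equal(disc[["g1"]], 60)  # earliest across datasets
  expect_equal(disc[["g3"]], 15)
  ev <- attr(cls, "evidence")
  expect_setequal(unique(ev$gene_id), c("g1", "g2", "g3"))
  expect_equal(ev$call[ev$gene_id == "g3" & ev$dataset == "plus"],
               rep("filtered", 3))
})

test_that("equivalence-at-discovery mode relaxes the all-timepoints rule", {
  ids <- c("g1")
  dplus <- dec_from(ids, de_tp = list(g1 = 60))
  # minus: equivalent at 60 only
  de <- matrix(FALSE, 1, 3, dimnames = list(ids, shared3))
  eq <- matrix(c(FALSE, TRUE, FALSE), 1, 3, dimnames = list(ids, shared3))
  dminus <- make_decision_table(ids, shared3, de, eq)
  fp <- make_filter_result(ids); fm <- make_filter_result(ids)
  strict <- classify_genes(dplus, dminus, fp, fm, shared3)
  relaxed <- classify_genes(dplus, dminus, fp, fm, shared3,
                            equivalence_mode = "de_timepoint_only")
  expect_equal(strict$class, "unclassified")
  expect_equal(relaxed$class, "SRP")
})

test_that("swapping datasets maps SRP <-> SRM and fixes the rest", {
  set.seed(41)
  for (r in 1:20) {
    G <- 50
    ids <- sprintf("g%02d", 1:G)
    rand_dec <- function() {
      de <- matrix(runif(G * 3) < 0.15, G, 3, dimnames = list(ids, shared3))
      eq <- matrix(runif(G * 3) < 0.4, G, 3, dimnames = list(ids, shared3))
      make_decision_table(ids, shared3, de, eq)
    }
    rand_filt <- function() {
      filt <- ids[runif(G) < 0.1]
      make_filter_result(setdiff(ids, filt), filt)
    }
    d1 <- rand_dec(); d2 <- rand_dec()
    f1 <- rand_filt(); f2 <- rand_filt()
    a <- classify_genes(d1, d2, f1, f2, shared3)
    b <- classify_genes(d2, d1, f2, f1, shared3)
    map <- c(SRB = "SRB", SRP = "SRM", SRM = "SRP",
             nonresponsive = "nonresponsive", unclassified = "unclassified")
    expect_equal(unname(map[a$class]), b$class[match(a$gene_id, b$gene_id)])
    # partition: every gene appears exactly once
    expect_equal(sort(a$gene_id), sort(ids))
  }
})

test_that("classification reports tabulate the partition exactly", {
  ids <- paste0("g", 1:4)
  dplus <- dec_from(ids, de_tp = list(g1 = 15, g2 = 60), equiv_genes = "g3")
  dminus <- dec_from(ids, de_tp = list(g1 = 60), equiv_genes = c("g2", "g3"))
  cls <- classify_genes(dplus, dminus, make_filter_result(ids),
                        make_filter_result(ids), shared3)
  rep <- classification_report(cls,
                               lfc_plus = setNames(c(2, -3, 0, 0), ids),
                               lfc_minus = setNames(c(1, 1, 0, 0), ids))
  expect_equal(sum(rep$class_counts), length(ids))
  expect_equal(as.integer(rep$class_counts[c("SRB", "SRP")]), c(1, 1))
  expect_equal(unname(rep$direction["SRP", "down"]), 1)
  empty <- classify_genes(dec_from("gX"), dec_from("gX"),
                          make_filter_result("gX"), make_filter_result("gX"),
                          shared3)
  expect_equal(sum(classification_report(empty)$class_counts[c("SRB", "SRP", "SRM")]), 0)
})
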