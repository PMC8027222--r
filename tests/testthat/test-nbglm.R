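test_that("cell-means designs have one column per nonempty cell", {
  sim <- simulate_experiment(small_sim_config())
  X <- build_design(sim$plus$samples)
  expect_equal(ncol(X), 11)  # 0h control + 5 timepoints x 2 conditions
  expect_equal(attr(X, "timepoints"), c(15, 60, 180, 360, 540))
  expect_true(all(colSums(X) == 3))
  X0 <- build_design(sim$plus$samples, "timepoint_only")
  expect_equal(ncol(X0), 6)
  # one timepoint, two conditions
  b <- make_null_bundle(G = 5)
  X2 <- build_design(b$samples)
  expect_equal(colnames(X2), c("t60_control", "t60_treated"))
})

test_that("control-only cells get a single parameter", {
  b <- make_null_bundle(G = 5)
  s <- as.data.frame(b$samples)
  s$condition <- "control"
  s$time_min <- NULL
  s$timepoint <- rep(c("15min", "1h"), each = 3)
  X <- build_design(sample_table(s))
  expect_equal(colnames(X), c("t15_control", "t60_control"))
  expect_equal(attr(X, "timepoints"), numeric(0))
})

test_that("intercept-only NB fit recovers the sample mean exactly", {
  X <- matrix(1, 3, 1, dimnames = list(paste0("s", 1:3), "mu"))
  for (phi in c(1e-4, 0.1, 1)) {
    f <- fit_gene(c(3, 5, 7), X, dispersion = phi)
    expect_equal(unname(exp(f$coefficients[1, 1])), 5, tolerance = 1e-6)
  }
})

test_that("saturated designs give zero deviance", {
  X <- diag(3)
  rownames(X) <- paste0("s", 1:3)
  colnames(X) <- paste0("c", 1:3)
  f <- fit_gene(c(4, 9, 2), X, dispersion = 0.2)
  expect_lt(abs(f$deviance), 1e-6)
})

test_that("NB fits at vanishing dispersion match a Poisson GLM oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    p <- sample(1:2, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    rownames(X) <- paste0("s", 1:n)
    colnames(X) <- paste0("c", 1:p)
    off <- runif(n, -0.5, 0.5)
    y <- rpois(n, lambda = exp(1 + off))
    if (sum(y) == 0) next
    oracle <- glm(y ~ 0 + X, family = poisson(), offset = off)
    f <- fit_gene(y, X, dispersion = 1e-8, offset = off)
    expect_equal(unname(f$coefficients[1, ]), unname(coef(oracle)),
                 tolerance = 1e-6)
  }
})

test_that("nb_deviance obeys its limits and additivity", {
  expect_equal(nb_deviance(c(3, 5), c(3, 5), 0.1), 0)
  y <- c(2, 4); mu <- c(3, 3)
  pois_dev <- 2 * sum(y * log(y / mu) - (y - mu))
  expect_equal(nb_deviance(y, mu, 1e-9), pois_dev, tolerance = 1e-6)
  expect_equal(nb_deviance(c(2, 4, 7), c(3, 3, 5), 0.2),
               nb_deviance(c(2, 4), c(3, 3), 0.2) +
                 nb_deviance(7, 5, 0.2), tolerance = 1e-12)
  # glmFit deviances agree with the closed form
  b <- make_null_bundle(G = 20, seed = 3)
  X <- build_design(b$samples)
  nf <- norm_factors(b)
  f <- fit_nbglm(b, X, dispersion = 0.1, factors = nf)
  g <- 5
  expect_equal(f$deviance[g],
               nb_deviance(b$counts[g, ], f$fitted[g, ], 0.1),
               tolerance = 1e-6)
})

test_that("adding a design column never increases the deviance", {
  b <- make_null_bundle(G = 50, seed = 9)
  X_full <- build_design(b$samples)
  X_red <- build_design(b$samples, "timepoint_only")
  nf <- norm_factors(b)
  f_full <- fit_nbglm(b, X_full, 0.1, nf)
  f_red <- fit_nbglm(b, X_red, 0.1, nf)
  expect_true(all(f_full$deviance <= f_red$deviance + 1e-6))
})

test_that("fits are invariant to co-permuting samples and design rows", {
  b <- make_null_bundle(G = 30, seed = 5)
  X <- build_design(b$samples)
  nf <- norm_factors(b)
  f1 <- fit_nbglm(b, X, 0.1, nf)
  perm <- c(4, 1, 6, 2, 5, 3)
  b2 <- b
  b2$counts <- b$counts[, perm]
  b2$samples <- b$samples[perm, ]
  X2 <- X[perm, ]
  attr(X2, "cells") <- attr(X, "cells")
  attr(X2, "timepoints") <- attr(X, "timepoints")
  nf2 <- nf[perm, ]
  f2 <- fit_nbglm(b2, X2, 0.1, nf2)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-8)
  expect_equal(f2$deviance, f1$deviance, tolerance = 1e-8)
})

test_that("tagwise dispersions recover the truth within +/-50%", {
  set.seed(21)
  G <- 2000; n <- 6
  for (phi in c(0.05, 0.1, 0.4)) {
    counts <- matrix(rnbinom(G * n, mu = 100, size = 1 / phi), G, n,
                     dimnames = list(sprintf("g%04d", 1:G), paste0("s", 1:n)))
    b <- make_two_group_bundle(counts)
    d <- estimate_dispersions(b, build_design(b$samples))
    med <- median(d$tagwise)
    expect_gte(med, 0.5 * phi)
    expect_lte(med, 1.5 * phi)
  }
})

test_that("Poisson data yield near-zero tagwise dispersions", {
  set.seed(22)
  G <- 2000; n <- 6
  counts <- matrix(rpois(G * n, lambda = 100), G, n,
                   dimnames = list(sprintf("g%04d", 1:G), paste0("s", 1:n)))
  b <- make_two_group_bundle(counts)
  d <- estimate_dispersions(b, build_design(b$samples))
  expect_lte(median(d$tagwise), 0.05)
})

test_that("infinite prior df shrinks tagwise onto the trend", {
  b <- make_null_bundle(G = 300, seed = 8)
  X <- build_design(b$samples)
  d <- estimate_dispersions(b, X, prior_df = 1e9)
  expect_equal(d$tagwise, d$trended, tolerance = 1e-6)
})
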