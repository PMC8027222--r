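test_that("Wald DE p-values match the normal reference", {
  expect_equal(wald_p_de(0, 1), 1)
  expect_equal(wald_p_de(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_p_de(-1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_p_de(3, 0), 1)  # degenerate se
})

test_that("threshold test reduces to the ordinary test at tau = 0", {
  set.seed(13)
  est <- rnorm(200); se <- rexp(200) + 0.05
  expect_equal(wald_p_threshold(est, se, 0), wald_p_de(est, se),
               tolerance = 1e-12)
})

test_that("threshold p at the boundary and monotonicity in tau", {
  se <- 0.3; tau <- log(3)
  p_boundary <- wald_p_threshold(tau, se, tau)
  expect_equal(p_boundary, 0.5 + pnorm(2 * tau / se, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(p_boundary, 0.5)
  taus <- seq(0, 3, length.out = 40)
  p <- wald_p_threshold(rep(1.2, 40), rep(0.25, 40), 0)
  p_grid <- vapply(taus, function(t) wald_p_threshold(1.2, 0.25, t), numeric(1))
  expect_true(all(diff(p_grid) >= -1e-12))
})

test_that("TOST boundary and limit behaviour", {
  tau <- log(3)
  expect_equal(tost_p_equivalence(tau, 0.4, tau), 0.5)
  expect_equal(tost_p_equivalence(-tau, 0.4, tau), 0.5)
  expect_lt(tost_p_equivalence(0, 1e-4, tau), 1e-10)
  expect_equal(tost_p_equivalence(NaN, 1, tau), 1)
})

test_that("TOST controls its type-I error at the margin", {
  set.seed(1)
  se <- 0.3; tau <- log(3)
  est <- rnorm(10000, mean = tau, sd = se)  # true effect exactly at margin
  rate <- mean(tost_p_equivalence(est, se, tau) <= 0.05)
  expect_lte(rate, 0.06)
})

test_that("TOST and threshold rejections are mutually exclusive", {
  set.seed(14)
  est <- rnorm(5000, sd = 2); se <- rexp(5000) + 0.05; tau <- log(3)
  both <- wald_p_threshold(est, se, tau) < 0.25 &
    tost_p_equivalence(est, se, tau) < 0.25
  expect_false(any(both))
})

test_that("contrast sign flips the LFC and leaves p-values unchanged", {
  b <- make_null_bundle(G = 40, seed = 4)
  X <- build_design(b$samples)
  nf <- norm_factors(b)
  f <- fit_nbglm(b, X, 0.1, nf)
  w <- treatment_contrasts(X)[[1]]
  expect_equal(test_de(f, w), test_de(f, -w), tolerance = 1e-12)
  expect_equal(test_de_threshold(f, w), test_de_threshold(f, -w),
               tolerance = 1e-12)
  expect_equal(test_equivalence(f, w), test_equivalence(f, -w),
               tolerance = 1e-12)
  ce1 <- sipresponse:::contrast_estimates(f, w)
  ce2 <- sipresponse:::contrast_estimates(f, -w)
  expect_equal(ce1$estimate, -ce2$estimate)
})

test_that("threshold test converges to the ordinary test as FC -> 1", {
  b <- make_null_bundle(G = 20, seed = 6)
  X <- build_design(b$samples)
  f <- fit_nbglm(b, X, 0.1, norm_factors(b))
  w <- treatment_contrasts(X)[[1]]
  expect_equal(test_de_threshold(f, w, fold_change = 1), test_de(f, w),
               tolerance = 1e-12)
  expect_equal(test_de_threshold(f, w, fold_change = 1 + 1e-12),
               test_de(f, w), tolerance = 1e-6)
})

test_that("DE and screen p-values are uniform under the null", {
  b <- make_null_bundle(G = 2000, mu = 100, phi = 0.1, seed = 1)
  X <- build_design(b$samples)
  X0 <- build_design(b$samples, "timepoint_only")
  nf <- norm_factors(b)
  d <- estimate_dispersions(b, X, nf)
  f <- fit_nbglm(b, X, d$tagwise, nf)
  f0 <- fit_nbglm(b, X0, d$tagwise, nf)
  w <- treatment_contrasts(X)[[1]]
  p_de <- test_de(f, w)
  expect_gt(ks.test(p_de, "punif")$p.value, 0.01)
  p_screen <- screen_omnibus(f, f0)
  expect_equal(attr(p_screen, "df"), 1)
  expect_gt(ks.test(as.numeric(p_screen), "punif")$p.value, 0.01)
})

test_that("the omnibus screen matches the chi-square reference", {
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
  b <- make_null_bundle(G = 10, seed = 2)
  X <- build_design(b$samples)
  f <- fit_nbglm(b, X, 0.1, norm_factors(b))
  p_same <- screen_omnibus(f, f)
  expect_equal(as.numeric(p_same), rep(1, 10))
})

test_that("zero-cell genes are flagged degenerate and never equivalent", {
  b <- make_null_bundle(G = 10, seed = 15)
  b$counts[1, b$samples$condition == "treated"] <- 0
  X <- build_design(b$samples)
  f <- fit_nbglm(b, X, 0.1, norm_factors(b))
  res <- test_contrasts(f, fold_change = 3)
  g1 <- res[res$gene_id == "g0001", ]
  expect_true(g1$degenerate)
  expect_equal(g1$p_equiv, 1)
})
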