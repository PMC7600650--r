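test_that("size factors follow the median-of-ratios definition", {
  # identical columns are already normalized
  m <- toy_counts(rep(c(5L, 10L, 20L), 4), 3, 4)
  expect_equal(unname(estimate_size_factors(m)), rep(1, 4))

  # doubling one column splits geometrically around the reference
  m2 <- toy_counts(c(4L, 8L, 8L, 8L, 16L, 16L), 3, 2)
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # brute-force application of the definition on a random matrix
  set.seed(7)
  m3 <- toy_counts(rpois(300, 50) + 1L, 50, 6)
  ref <- apply(m3, 2, function(col) {
    geo <- exp(rowMeans(log(m3)))
    median(col / geo)
  })
  expect_equal(estimate_size_factors(m3), ref)

  # equivariance under sample permutation
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(unname(estimate_size_factors(m3[, perm])),
               unname(estimate_size_factors(m3))[perm])

  expect_error(estimate_size_factors(toy_counts(c(0L, 1L, 1L, 0L), 2, 2)),
               "strictly positive")
})

test_that("size factors agree with the established reference implementation", {
  skip_if_not_installed("DESeq2")
  # odd feature count: the reference's log-scale median and this package's
  # ratio-scale median (arithmetic mean of central ratios when even)
  # coincide exactly
  set.seed(42)
  m <- toy_counts(rnbinom(101 * 6, mu = 80, size = 5) + 1L, 101, 6)
  expect_equal(unname(estimate_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("log2 expression transform is exact and monotone", {
  m <- toy_counts(c(0L, 7L), 2, 1)
  sf <- c(S01 = 1)
  lx <- log2_expression(m, sf, pseudocount = 1)
  expect_equal(unname(lx[, 1]), c(0, 3))
  expect_identical(dimnames(lx), dimnames(m))

  set.seed(1)
  for (rep in 1:20) {
    a <- sample.int(1000, 2)
    mm <- toy_counts(sort(a), 2, 1)
    v <- log2_expression(mm, sf, pseudocount = 0.5)
    expect_true(v[2, 1] > v[1, 1])
  }
  expect_error(log2_expression(m, sf, pseudocount = 0), "positive")
})

test_that("moment dispersion recovers the truth and flags degenerate rows", {
  X <- cbind(1, rep(c(0, 1), c(10, 9)))
  sf <- rep(1, 19)
  # Poisson data: estimates collapse to the lower bound in the median
  set.seed(21)
  pois <- toy_counts(rpois(500 * 19, 100), 500, 19)
  d_pois <- estimate_dispersion(pois, X, sf)
  expect_lt(median(d_pois), 0.02)

  # NB data at alpha = 0.5 with many samples: median within [0.35, 0.65]
  X2 <- cbind(1, rep(c(0, 1), each = 50))
  set.seed(22)
  nb <- toy_counts(rnbinom(500 * 100, mu = 200, size = 2), 500, 100)
  d_nb <- estimate_dispersion(nb, X2, rep(1, 100))
  expect_gt(median(d_nb), 0.35)
  expect_lt(median(d_nb), 0.65)

  # all-zero features are not fitted
  z <- rbind(F01 = rep(0L, 19), F02 = rpois(19, 5))
  colnames(z) <- sprintf("S%02d", 1:19)
  d_z <- estimate_dispersion(z, X, sf)
  expect_true(is.na(d_z[1]) && !is.na(d_z[2]))
})

test_that("wald test reports no signal for constant features", {
  m <- toy_counts(50L, 3, 16)
  res <- wald_test(m, toy_samples(8), "EXAC:CTL", covariates = character(0),
                   size_factors = setNames(rep(1, 16), colnames(m)))
  expect_true(all(abs(res$log2fc) < 1e-6))
  expect_true(all(res$pvalue > 0.99))
  expect_true(all(res$tested & res$converged))
})

test_that("wald test recovers a planted log2 fold change of 2", {
  set.seed(1)
  n <- 500
  mu0 <- rlnorm(n, log(200), 1)
  mu <- cbind(matrix(rep(mu0, 8), n), matrix(rep(mu0 * 4, 8), n))
  rownames(mu) <- sprintf("F%03d", seq_len(n))
  colnames(mu) <- sprintf("S%02d", 1:16)
  counts <- sample_nb_counts(mu, 0.1)
  res <- wald_test(counts, toy_samples(8, c("CTL", "EXAC")), "EXAC:CTL",
                   covariates = character(0),
                   size_factors = setNames(rep(1, 16), colnames(counts)))
  expect_gt(mean(res$log2fc), 1.9)
  expect_lt(mean(res$log2fc), 2.1)
})

test_that("raw p-values are calibrated under the global null", {
  set.seed(5)
  n <- 2000
  mu0 <- rlnorm(n, log(150), 1)
  mu <- matrix(rep(mu0, 16), n)
  rownames(mu) <- sprintf("F%04d", seq_len(n))
  colnames(mu) <- sprintf("S%02d", 1:16)
  counts <- sample_nb_counts(mu, 0.2)
  res <- wald_test(counts, toy_samples(8), "EXAC:CTL",
                   covariates = character(0),
                   size_factors = setNames(rep(1, 16), colnames(counts)))
  frac <- mean(res$pvalue <= 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("reversing the contrast flips the log2FC sign exactly", {
  ds <- generate_dataset(sim_config(n_mirna = 30, n_gene = 10,
                                    n_regulatory_pairs = 0,
                                    n_decoy_interactions = 0, seed = 13))
  a <- wald_test(ds$mirna_counts, ds$samples, "EXAC:CTL")
  b <- wald_test(ds$mirna_counts, ds$samples, "CTL:EXAC")
  ok <- a$converged & b$converged
  expect_true(all(abs(a$log2fc[ok] + b$log2fc[ok]) < 1e-6))
  expect_equal(a$pvalue[ok], b$pvalue[ok], tolerance = 1e-9)
})

test_that("the IRLS fitter matches an independent GLM fit at fixed dispersion", {
  skip_if_not_installed("MASS")
  set.seed(9)
  X <- cbind(1, rep(c(0, 1), each = 10), runif(20))
  mu <- exp(4 + 0.8 * X[, 2] + 0.3 * X[, 3])
  alpha <- 0.25
  y <- rnbinom(20, mu = mu, size = 1 / alpha)
  counts <- matrix(y, 1, 20)
  fit <- mirmint:::nb_glm_fit_matrix(counts, X, rep(0, 20), alpha)
  ref <- glm(y ~ X - 1, family = MASS::negative.binomial(theta = 1 / alpha))
  expect_equal(as.numeric(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_true(fit$converged[1])
})

test_that("BH step-up matches its definition and the stats implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone in sorted order and bounded by the raw values and 1
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p - 1e-15 & q <= 1))
  }
  expect_error(bh_adjust(c(0.1, NA)), "missing")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("significance selection is inclusive at the threshold", {
  empty <- data.frame(feature_id = character(0), padj = numeric(0))
  expect_identical(select_significant(empty), character(0))
  res <- data.frame(feature_id = c("a", "b", "c"),
                    padj = c(0.05, 0.049, 0.051))
  expect_identical(select_significant(res, 0.05), c("a", "b"))
})

test_that("significant set recovers planted DE features on synthetic data", {
  ds <- generate_dataset(sim_config(n_mirna = 5, n_gene = 300,
                                    de_fraction = 0.1,
                                    de_log2fc_range = c(2, 3),
                                    n_regulatory_pairs = 0,
                                    n_decoy_interactions = 0, seed = 17))
  res <- wald_test(ds$mrna_counts, ds$samples, "EXAC:CTL")
  sig <- select_significant(res, 0.05)
  truth <- ds$truth$de[["EXAC:CTL"]]
  truth_genes <- truth$feature_id[truth$kind == "mRNA"]
  recall <- length(intersect(sig, truth_genes)) / length(truth_genes)
  expect_gt(recall, 0.5)
  # most selections are planted features
  expect_gt(length(intersect(sig, truth_genes)) / max(1, length(sig)), 0.7)
})
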