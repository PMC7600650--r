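test_that("pearson_r matches the textbook formula and flags constants", {
  expect_equal(pearson_r(1:4, c(8, 6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 3, 2, 5), c(1, 3, 2, 5)), 1)
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(13); y <- rnorm(13)
    manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), manual, tolerance = 1e-12)
  }
  expect_true(is.na(pearson_r(rep(1, 5), rnorm(5))))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson p-values match t-density quadrature", {
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_equal(pearson_pvalue(1, 10), 0)
  expect_equal(pearson_pvalue(-1, 5), 0)
  for (case in list(c(-0.7, 15), c(0.3, 8), c(-0.95, 6))) {
    r <- case[1]; n <- case[2]
    tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
    quad <- 2 * integrate(function(x) dt(x, n - 2), tstat, Inf)$value
    expect_equal(pearson_pvalue(r, n), quad, tolerance = 1e-6)
  }
  expect_error(pearson_pvalue(0.5, 2), "n >= 3")
})

test_that("screen is empty when either DE set is empty", {
  ds <- generate_dataset(sim_config(n_mirna = 5, n_gene = 10,
                                    n_regulatory_pairs = 2,
                                    n_decoy_interactions = 5, seed = 2))
  lm_mi <- log2_expression(ds$mirna_counts)
  lm_mg <- log2_expression(ds$mrna_counts)
  expect_equal(nrow(negative_correlation_screen(lm_mi, lm_mg, character(0),
                                                rownames(lm_mg))), 0)
  expect_equal(nrow(negative_correlation_screen(lm_mi, lm_mg,
                                                rownames(lm_mi), character(0))), 0)
})

test_that("screen retains the planted pair and never a positive one", {
  cfg <- sim_config(n_regulatory_pairs = 1, repression_strength_gamma = 1.5,
                    n_decoy_interactions = 0, seed = 1)
  ds <- generate_dataset(cfg)
  pair <- ds$truth$pairs
  res <- negative_correlation_screen(
    log2_expression(ds$mirna_counts), log2_expression(ds$mrna_counts),
    de_mirnas = pair$mirna_id, de_genes = pair$gene_id)
  expect_equal(nrow(res), 1)
  expect_lt(res$r, 0)

  # an activating relationship (positive correlation) can never be retained
  up <- matrix(rep(1:10, 2), 2, 10, byrow = TRUE) + matrix(rpois(20, 2), 2)
  rownames(up) <- c("eca-miR-1", "ignore")
  colnames(up) <- sprintf("S%02d", 1:10)
  gene <- up; rownames(gene) <- c("GENEUP", "ignore2")
  res_up <- negative_correlation_screen(log2(up + 1), log2(gene + 1),
                                        "eca-miR-1", "GENEUP")
  expect_equal(nrow(res_up), 0)
})

test_that("provisional miRNAs are excluded and retained pairs obey the contract", {
  ds <- generate_dataset(sim_config(seed = 4))
  td <- ds$truth$de[["EXAC:CTL"]]
  de_mi <- td$feature_id[td$kind == "miRNA"]
  res <- negative_correlation_screen(
    log2_expression(ds$mirna_counts), log2_expression(ds$mrna_counts),
    de_mi, td$feature_id[td$kind == "mRNA"])
  expect_false(any(is_provisional_mirna(res$mirna_id)))
  expect_true(all(res$r < 0))
  expect_true(all(res$padj <= 0.05))
  expect_true(all(res$padj >= res$pvalue - 1e-15))
  expect_true(all(res$n == 19))

  # retained set does not depend on the enumeration order of the DE sets
  res2 <- negative_correlation_screen(
    log2_expression(ds$mirna_counts), log2_expression(ds$mrna_counts),
    rev(de_mi), rev(td$feature_id[td$kind == "mRNA"]))
  expect_identical(res[order(res$mirna_id, res$gene_id), c("mirna_id", "gene_id", "r")],
                   res2[order(res2$mirna_id, res2$gene_id), c("mirna_id", "gene_id", "r")])
})

test_that("database-support filter keeps supported pairs with counts", {
  pairs <- data.frame(mirna_id = c("eca-miR-1", "eca-miR-2", "eca-miR-3"),
                      gene_id = c("GA", "GB", "GC"),
                      r = c(-0.9, -0.8, -0.7), n = 10,
                      pvalue = c(1e-4, 1e-3, 1e-2),
                      padj = c(3e-4, 2e-3, 2e-2), stringsAsFactors = FALSE)
  tabs <- list(
    data.frame(mirna_id = c("hsa-miR-1", "hsa-miR-2"), gene_id = c("GA", "GB"),
               db_name = "dbA", stringsAsFactors = FALSE),
    data.frame(mirna_id = "hsa-miR-1", gene_id = "ga", db_name = "dbB",
               stringsAsFactors = FALSE),
    data.frame(mirna_id = "hsa-miR-9", gene_id = "GZ", db_name = "dbC",
               stringsAsFactors = FALSE),
    data.frame(mirna_id = character(0), gene_id = character(0),
               db_name = character(0), stringsAsFactors = FALSE))
  out <- filter_db_support(pairs, tabs)
  expect_identical(out$mirna_id, c("eca-miR-1", "eca-miR-2"))
  expect_identical(out$db_support, c(2, 1))
  expect_identical(out$dbs[1], "dbA,dbB")

  # unmappable (provisional) miRNA pairs are dropped with a warning
  pairs$mirna_id[3] <- "eca-miR-chrX_37753"
  expect_warning(out2 <- filter_db_support(pairs, tabs), "unmappable")
  expect_false("eca-miR-chrX_37753" %in% out2$mirna_id)
})

test_that("database filtering never worsens precision on the benchmark", {
  ds <- generate_dataset(sim_config(seed = 1))
  td <- ds$truth$de[["EXAC:CTL"]]
  sc <- negative_correlation_screen(
    log2_expression(ds$mirna_counts), log2_expression(ds$mrna_counts),
    td$feature_id[td$kind == "miRNA"], td$feature_id[td$kind == "mRNA"])
  kept <- filter_db_support(sc, ds$interactions)
  tkey <- paste(ds$truth$pairs$mirna_id, ds$truth$pairs$gene_id)
  prec <- function(df) if (nrow(df) == 0) 1 else
    mean(paste(df$mirna_id, df$gene_id) %in% tkey)
  expect_gte(prec(kept), prec(sc))
})

test_that("pair summaries use the n-1 standard deviation and 2-decimal reporting", {
  s <- summarize_pairs(data.frame(r = c(-0.5)))
  expect_equal(s$mean_r, -0.5)
  expect_equal(s$sd_r, 0)
  s2 <- summarize_pairs(c(-0.7, -0.8))
  expect_equal(s2$sd_r, sd(c(-0.7, -0.8)))
  expect_equal(summarize_pairs(numeric(0))$n_pairs, 0L)
  # half-away rounding at the boundary
  expect_equal(round_half_away(-0.775, 2), -0.78)
  expect_equal(round_half_away(0.125, 2), 0.13)
})

test_that("contrast overlaps perform exact set algebra", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "z", "w"), C = c("q"))
  ov <- contrast_overlap(sets)
  ms <- attr(ov, "member_sets")
  expect_identical(ms[["A & B"]], c("y", "z"))
  expect_identical(ms[["A & C"]], character(0))
  expect_identical(ms[["A & B & C"]], character(0))
  expect_equal(ov$size[ov$contrasts == "A & B"], 2)
  expect_error(contrast_overlap(list(A = "x")), "2")
})
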