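#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of the end-to-end analysis.
#' Inputs are in-memory objects (use the readers in this package to load
#' them from disk).
#'
#' @param mirna_counts,mrna_counts count matrices sharing sample columns.
#' @param samples sample sheet (`sample_id`, `group`, covariates).
#' @param interactions list of interaction data.frames, one per database.
#' @param contrasts list of length-2 group vectors; defaults to
#'   EXAC vs CTL, REM vs CTL, EXAC vs REM.
#' @param covariates sample-sheet columns adjusted for in the DE model.
#' @param alpha_de,alpha_corr inclusive BH thresholds for differential
#'   expression and for the correlation screen (defaults 0.05).
#' @param pseudocount pseudocount of the log2 expression transform.
#' @param correlation_samples `"contrast"` restricts each correlation
#'   screen to the contrast's two groups; `"all"` uses every sample.
#' @param novel_seqs,reference_seqs optional named mature-sequence vectors
#'   enabling the homology stage.
#' @param homolog_threshold identity threshold for homolog classification.
#' @param id_map optional miRNA namespace override table.
#' @param out_dir optional output directory; when set, every stage writes
#'   its tables there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mirna_counts, mrna_counts, samples, interactions,
                            contrasts = list(c("EXAC", "CTL"),
                                             c("REM", "CTL"),
                                             c("EXAC", "REM")),
                            covariates = c("sex", "batch"),
                            alpha_de = 0.05, alpha_corr = 0.05,
                            pseudocount = 1,
                            correlation_samples = c("contrast", "all"),
                            novel_seqs = NULL, reference_seqs = NULL,
                            homolog_threshold = 0.90, id_map = NULL,
                            out_dir = NULL) {
  correlation_samples <- match.arg(correlation_samples)
  check_count_matrix(mirna_counts)
  check_count_matrix(mrna_counts)
  check_sample_sheet(samples, mirna_counts)
  check_sample_sheet(samples, mrna_counts)
  stopifnot(alpha_de > 0, alpha_de < 1, alpha_corr > 0, alpha_corr < 1)
  for (ct in contrasts) {
    ct <- parse_contrast(ct)
    if (!all(ct %in% samples$group)) stop("contrast group missing from sample sheet")
  }
  structure(list(mirna_counts = mirna_counts, mrna_counts = mrna_counts,
                 samples = samples, interactions = interactions,
                 contrasts = contrasts, covariates = covariates,
                 alpha_de = alpha_de, alpha_corr = alpha_corr,
                 pseudocount = pseudocount,
                 correlation_samples = correlation_samples,
                 novel_seqs = novel_seqs, reference_seqs = reference_seqs,
                 homolog_threshold = homolog_threshold, id_map = id_map,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the integrative miRNA-mRNA analysis end to end
#'
#' For each contrast: differential expression of miRNAs and mRNAs
#' (NB Wald test with covariates), selection at the DE threshold, the
#' negative-correlation screen over DE miRNA x DE gene pairs with
#' interaction-database support, and the bipartite regulatory network.
#' Afterwards: cross-contrast overlaps of the DE miRNA sets and, when
#' mature sequences are supplied, seed-based homolog classification of the
#' provisional miRNAs. All outputs are deterministically ordered.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle` list with elements `de_mirna`, `de_mrna`,
#'   `pairs`, `summaries`, `networks` (per contrast), `overlap`,
#'   `homology` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sf_mi <- estimate_size_factors(config$mirna_counts)
  sf_mg <- estimate_size_factors(config$mrna_counts)
  log2_mi <- log2_expression(config$mirna_counts, sf_mi, config$pseudocount)
  log2_mg <- log2_expression(config$mrna_counts, sf_mg, config$pseudocount)

  ct_labels <- vapply(config$contrasts,
                      function(ct) paste(parse_contrast(ct), collapse = ":"),
                      character(1))
  de_mirna <- de_mrna <- pairs <- networks <- summaries <- list()
  for (k in seq_along(config$contrasts)) {
    ct <- parse_contrast(config$contrasts[[k]])
    lab <- ct_labels[k]
    de_mi <- wald_test(config$mirna_counts, config$samples, ct,
                       covariates = config$covariates, size_factors = sf_mi)
    de_mg <- wald_test(config$mrna_counts, config$samples, ct,
                       covariates = config$covariates, size_factors = sf_mg)
    sig_mi <- select_significant(de_mi, config$alpha_de)
    sig_mg <- select_significant(de_mg, config$alpha_de)

    sample_ids <- if (config$correlation_samples == "contrast")
      config$samples$sample_id[config$samples$group %in% ct]
    else config$samples$sample_id
    screened <- negative_correlation_screen(log2_mi, log2_mg, sig_mi, sig_mg,
                                            sample_ids = sample_ids,
                                            alpha = config$alpha_corr)
    supported <- filter_db_support(screened, config$interactions,
                                   id_map = config$id_map)

    lfc_mi <- setNames(de_mi$log2fc, de_mi$feature_id)[
      setdiff(sig_mi, sig_mi[is_provisional_mirna(sig_mi)])]
    lfc_mg <- setNames(de_mg$log2fc, de_mg$feature_id)[sig_mg]
    net <- build_network(lfc_mi, lfc_mg, config$interactions,
                         id_map = config$id_map, contrast = ct)

    de_mirna[[lab]] <- de_mi
    de_mrna[[lab]] <- de_mg
    pairs[[lab]] <- supported
    summaries[[lab]] <- summarize_pairs(supported)
    networks[[lab]] <- net
  }

  overlap <- contrast_overlap(lapply(de_mirna, select_significant,
                                     alpha = config$alpha_de))

  homology <- NULL
  if (!is.null(config$novel_seqs) && !is.null(config$reference_seqs)) {
    homology <- classify_homologs(config$novel_seqs, config$reference_seqs,
                                  config$homolog_threshold)
  }

  bundle <- structure(
    list(de_mirna = de_mirna, de_mrna = de_mrna, pairs = pairs,
         summaries = summaries, networks = networks, overlap = overlap,
         homology = homology, contrasts = ct_labels),
    class = "report_bundle")
  if (!is.null(config$out_dir)) bundle$manifest <- write_bundle(bundle, config$out_dir)
  bundle
}

# internal: write every bundle table; returns the manifest
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <<- c(manifest, file)
  }
  for (lab in bundle$contrasts) {
    tag <- gsub(":", "_vs_", lab)
    emit(bundle$de_mirna[[lab]], sprintf("de_mirna_%s.tsv", tag))
    emit(bundle$de_mrna[[lab]], sprintf("de_mrna_%s.tsv", tag))
    emit(bundle$pairs[[lab]], sprintf("pairs_%s.tsv", tag))
    export_graphml(bundle$networks[[lab]], file.path(dir, sprintf("network_%s.graphml", tag)))
    manifest <- c(manifest, sprintf("network_%s.graphml", tag))
  }
  emit(bundle$overlap, "overlap.tsv")
  if (!is.null(bundle$homology)) emit(bundle$homology, "homology.tsv")
  jsonlite::write_json(bundle$summaries, file.path(dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(manifest, "summaries.json")
  manifest
}

# internal: path to a packaged reference fixture
fixture_path <- function(file) {
  system.file("extdata", "reference_tables", file, package = "mirmint",
              mustWork = TRUE)
}

#' Load the packaged reference result tables
#'
#' Curated fixture tables transcribing the published differential-expression
#' and correlation-pair results of an equine asthma lung study: per-contrast
#' DE miRNA lists and retained negatively correlated miRNA-mRNA pairs, plus
#' mature sequences of the novel miRNA candidates.
#'
#' @return list with `de_mirna` (three data.frames), `pairs` (three
#'   data.frames) and `novel_seqs` (named sequence vector).
#' @export
reference_fixtures <- function() {
  de <- lapply(c(`EXAC:CTL` = "de_mirna_exac_vs_ctl.tsv",
                 `REM:CTL` = "de_mirna_rem_vs_ctl.tsv",
                 `EXAC:REM` = "de_mirna_exac_vs_rem.tsv"),
               function(f) read.delim(fixture_path(f), stringsAsFactors = FALSE))
  pairs <- lapply(c(`EXAC:CTL` = "pairs_exac_vs_ctl.tsv",
                    `REM:CTL` = "pairs_rem_vs_ctl.tsv",
                    `EXAC:REM` = "pairs_exac_vs_rem.tsv"),
                  function(f) read.delim(fixture_path(f), stringsAsFactors = FALSE))
  novel <- read_mirna_fasta(fixture_path("novel_mirna_mature.fasta"))
  list(de_mirna = de, pairs = pairs, novel_seqs = novel)
}

#' Recompute the in-study arithmetic checks from the packaged fixtures
#'
#' Recomputes, from the packaged reference tables, the quantities that can
#' be verified by desk arithmetic: cross-contrast DE miRNA overlaps, the
#' number of distinct provisional (novel) DE miRNAs, and the per-contrast
#' mean and standard deviation of the retained Pearson coefficients, each
#' compared with its published value at 2-decimal rounding.
#'
#' @return data.frame with columns `check`, `value`, `expected`, `pass`.
#' @export
check_reference_fixtures <- function() {
  fx <- reference_fixtures()
  ids <- lapply(fx$de_mirna, `[[`, "mirna_id")
  ov <- contrast_overlap(ids)
  ms <- attr(ov, "member_sets")
  novel_union <- unique(unlist(lapply(ids, function(x) x[is_provisional_mirna(x)])))
  s11 <- summarize_pairs(fx$pairs[["EXAC:CTL"]])
  s12 <- summarize_pairs(fx$pairs[["REM:CTL"]])
  s13 <- summarize_pairs(fx$pairs[["EXAC:REM"]])

  checks <- list(
    list("shared DE miRNAs, EXAC:CTL & REM:CTL",
         length(ms[["EXAC:CTL & REM:CTL"]]), 3),
    list("shared DE miRNAs, EXAC:CTL & EXAC:REM",
         length(ms[["EXAC:CTL & EXAC:REM"]]), 1),
    list("shared DE miRNAs, REM:CTL & EXAC:REM",
         length(ms[["REM:CTL & EXAC:REM"]]), 1),
    list("distinct novel DE miRNAs", length(novel_union), 6),
    list("EXAC:CTL retained pairs", s11$n_pairs, 14),
    list("EXAC:CTL mean r", s11$mean_r_2dp, -0.75),
    list("EXAC:CTL sd r", s11$sd_r_2dp, 0.08),
    list("REM:CTL retained pairs", s12$n_pairs, 4),
    list("REM:CTL mean r", s12$mean_r_2dp, -0.78),
    list("EXAC:REM retained pairs", s13$n_pairs, 2),
    list("EXAC:REM mean r", s13$mean_r_2dp, -0.82))
  out <- data.frame(
    check = vapply(checks, `[[`, character(1), 1),
    value = vapply(checks, function(x) as.numeric(x[[2]]), numeric(1)),
    expected = vapply(checks, function(x) as.numeric(x[[3]]), numeric(1)),
    stringsAsFactors = FALSE)
  out$pass <- out$value == out$expected
  # membership checks beyond counts
  shared <- ms[["EXAC:CTL & REM:CTL"]]
  if (!setequal(shared, c("eca-miR-142-3p", "eca-miR-142-5p", "eca-miR-223")))
    out$pass[1] <- FALSE
  if (!identical(ms[["EXAC:CTL & EXAC:REM"]], "eca-miR-31")) out$pass[2] <- FALSE
  out
}
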