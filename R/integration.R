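#' Pearson product-moment correlation
#'
#' Standard Pearson correlation of two equal-length vectors. A constant
#' vector leaves the coefficient undefined; the result is then `NA` (the
#' pair is excluded downstream rather than raising an error).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Based on the exact null distribution of
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom;
#' `|r| = 1` yields the limiting p-value 0.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @param n number of paired observations, >= 3.
#' @return p-value(s) in `[0, 1]`.
#' @export
pearson_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must not exceed 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) == 1, 0,
              2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  p
}

#' Screen DE miRNA x DE gene pairs for negative correlation
#'
#' Forms every pair of a differentially expressed, annotated miRNA with a
#' differentially expressed gene, computes the Pearson correlation of their
#' log2 normalized expression over the selected samples, BH-adjusts the
#' p-values over all candidate pairs, and retains pairs with `r < 0` and
#' `padj <= alpha`. Provisional (novel) miRNA identifiers are excluded
#' before pairing; pairs with a constant expression vector are excluded
#' from the family.
#'
#' @param log2_mirna,log2_mrna log2 expression matrices (features x
#'   samples) sharing sample columns, e.g. from [log2_expression()].
#' @param de_mirnas,de_genes character vectors of DE feature identifiers.
#' @param sample_ids optional sample subset to correlate over (default: all
#'   shared columns); per-contrast screens pass the contrast's samples.
#' @param alpha BH-adjusted significance threshold, inclusive
#'   (default 0.05).
#' @return data.frame of retained pairs with columns `mirna_id`, `gene_id`,
#'   `r`, `n`, `pvalue`, `padj`, ordered by `padj`, then `r`, then
#'   identifiers. The total candidate-family size is attached as attribute
#'   `n_candidates`.
#' @export
negative_correlation_screen <- function(log2_mirna, log2_mrna,
                                        de_mirnas, de_genes,
                                        sample_ids = NULL, alpha = 0.05) {
  empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                      r = numeric(0), n = integer(0),
                      pvalue = numeric(0), padj = numeric(0),
                      stringsAsFactors = FALSE)
  de_mirnas <- setdiff(de_mirnas, de_mirnas[is_provisional_mirna(de_mirnas)])
  de_mirnas <- intersect(de_mirnas, rownames(log2_mirna))
  de_genes <- intersect(de_genes, rownames(log2_mrna))
  if (length(de_mirnas) == 0 || length(de_genes) == 0) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  if (is.null(sample_ids))
    sample_ids <- intersect(colnames(log2_mirna), colnames(log2_mrna))
  if (length(sample_ids) < 3) stop("need at least 3 samples")

  A <- log2_mirna[de_mirnas, sample_ids, drop = FALSE]
  B <- log2_mrna[de_genes, sample_ids, drop = FALSE]
  n <- length(sample_ids)
  # feature-by-feature correlation matrix; constant rows give NA via zero sd
  sds_a <- apply(A, 1, sd)
  sds_b <- apply(B, 1, sd)
  R <- suppressWarnings(cor(t(A), t(B)))
  R[sds_a == 0, ] <- NA
  R[, sds_b == 0] <- NA

  cand <- expand.grid(mirna_id = de_mirnas, gene_id = de_genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand$r <- R[cbind(match(cand$mirna_id, de_mirnas),
                    match(cand$gene_id, de_genes))]
  cand <- cand[!is.na(cand$r), , drop = FALSE]
  if (nrow(cand) == 0) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  cand$n <- n
  cand$pvalue <- pearson_pvalue(cand$r, n)
  cand$padj <- bh_adjust(cand$pvalue)
  keep <- cand$r < 0 & cand$padj <= alpha
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$padj, out$r, out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- nrow(cand)
  out
}

#' Filter correlation pairs by interaction-database support
#'
#' Keeps pairs whose (miRNA, gene) interaction is listed in at least one of
#' the supplied databases, matching miRNA identifiers through the
#' human-namespace mapping (see [map_mirna_ids()]) and gene symbols
#' case-insensitively. Pairs whose miRNA cannot be mapped are dropped with
#' a warning.
#'
#' @param pairs a [negative_correlation_screen()] result.
#' @param interactions list of interaction data.frames (columns `mirna_id`,
#'   `gene_id`, `db_name`), one per database.
#' @param id_map optional override data.frame (`from`, `to`) for the
#'   namespace mapping.
#' @return the retained rows of `pairs` with added integer `db_support` and
#'   comma-separated `dbs` columns.
#' @export
filter_db_support <- function(pairs, interactions, id_map = NULL) {
  stopifnot(is.data.frame(pairs))
  if (is.data.frame(interactions)) interactions <- list(interactions)
  mapped <- map_mirna_ids(pairs$mirna_id, override = id_map)
  if (anyNA(mapped) && nrow(pairs) > 0) {
    warning("dropping pairs with unmappable miRNA identifiers: ",
            paste(unique(pairs$mirna_id[is.na(mapped)]), collapse = ", "))
  }
  keys <- paste(tolower(mapped), tolower(pairs$gene_id), sep = "\1")
  support <- matrix(FALSE, nrow(pairs), length(interactions))
  db_names <- character(length(interactions))
  for (k in seq_along(interactions)) {
    tab <- interactions[[k]]
    db_names[k] <- if (nrow(tab) > 0) tab$db_name[1] else
      if (!is.null(names(interactions))) names(interactions)[k] else as.character(k)
    tab_keys <- paste(tolower(tab$mirna_id), tolower(tab$gene_id), sep = "\1")
    support[, k] <- !is.na(mapped) & keys %in% tab_keys
  }
  n_support <- rowSums(support)
  keep <- which(n_support >= 1)
  out <- pairs[keep, , drop = FALSE]
  out$db_support <- n_support[keep]
  out$dbs <- vapply(keep, function(i) paste(db_names[support[i, ]], collapse = ","),
                    character(1))
  rownames(out) <- NULL
  out
}

#' Summarize retained correlation pairs
#'
#' Number of pairs, arithmetic mean and sample standard deviation (n - 1
#' denominator; 0 for a single pair) of the Pearson coefficients, plus
#' 2-decimal reporting values rounded half away from zero.
#'
#' @param pairs data.frame with an `r` column, or a numeric vector of
#'   coefficients.
#' @return list with `n_pairs`, `mean_r`, `sd_r`, `mean_r_2dp`, `sd_r_2dp`.
#'   An empty input yields `n_pairs = 0` and `NA` summaries.
#' @export
summarize_pairs <- function(pairs) {
  r <- if (is.data.frame(pairs)) pairs$r else as.numeric(pairs)
  if (length(r) == 0)
    return(list(n_pairs = 0L, mean_r = NA_real_, sd_r = NA_real_,
                mean_r_2dp = NA_real_, sd_r_2dp = NA_real_))
  m <- mean(r)
  s <- if (length(r) == 1) 0 else sd(r)
  list(n_pairs = length(r), mean_r = m, sd_r = s,
       mean_r_2dp = round_half_away(m, 2), sd_r_2dp = round_half_away(s, 2))
}

#' Cross-contrast overlaps of feature sets
#'
#' Exact set algebra over named feature sets: every pairwise and
#' higher-order intersection with its members and size.
#'
#' @param feature_sets named list of >= 2 character vectors.
#' @return data.frame with columns `contrasts` (names joined by `" & "`),
#'   `degree` (number of sets intersected), `size`, and `members`
#'   (semicolon-joined, sorted). The member sets themselves are attached as
#'   the attribute `member_sets`.
#' @export
contrast_overlap <- function(feature_sets) {
  stopifnot(is.list(feature_sets), length(feature_sets) >= 2,
            !is.null(names(feature_sets)))
  nm <- names(feature_sets)
  combos <- list()
  for (k in 2:length(nm)) {
    cb <- utils::combn(nm, k, simplify = FALSE)
    combos <- c(combos, cb)
  }
  members <- lapply(combos, function(cb) sort(Reduce(intersect, feature_sets[cb])))
  out <- data.frame(
    contrasts = vapply(combos, paste, character(1), collapse = " & "),
    degree = vapply(combos, length, integer(1)),
    size = vapply(members, length, integer(1)),
    members = vapply(members, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  attr(out, "member_sets") <- setNames(members, out$contrasts)
  out
}
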