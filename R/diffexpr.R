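#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed by the median-of-ratios
#' method: a pseudo-reference is built as the per-feature geometric mean
#' across samples, and each sample's size factor is the median, over the
#' features with strictly positive counts in every sample, of the ratio
#' count / geometric mean. With an even number of usable features the median
#' is the arithmetic mean of the two central ratios.
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   row and column names.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  check_count_matrix(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) stop("no feature has strictly positive counts in every sample")
  geo <- exp(rowMeans(log(counts[use, , drop = FALSE])))
  # medians on the ratio scale: an even feature count averages the two
  # central ratios themselves, not their logs
  sf <- apply(counts[use, , drop = FALSE] / geo, 2, median)
  setNames(sf, colnames(counts))
}

#' Normalized log2 expression
#'
#' Size-factor-normalized counts on the log2 scale,
#' `log2(count / size_factor + pseudocount)`, the expression scale used for
#' the miRNA-gene correlation screen.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param size_factors positive per-sample factors (defaults to
#'   [estimate_size_factors()]).
#' @param pseudocount positive value added before the log (default 1).
#' @return numeric matrix with the same dimnames as `counts`.
#' @export
log2_expression <- function(counts, size_factors = NULL, pseudocount = 1) {
  check_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
    stop("size_factors must be positive, one per sample")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  log2(sweep(counts, 2, size_factors, "/") + pseudocount)
}

# internal: design matrix for intercept + group + covariates on a sample
# subset; denominator group is the reference level so the group coefficient
# is log(numerator/denominator)
build_design <- function(samples, contrast, covariates) {
  grp <- factor(samples$group, levels = c(contrast[2], contrast[1]))
  df <- data.frame(group = grp)
  for (cv in covariates) {
    v <- factor(samples[[cv]])
    if (nlevels(droplevels(v)) > 1) df[[cv]] <- droplevels(v)
  }
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  X
}

#' Per-feature negative-binomial dispersion
#'
#' Method-of-moments dispersion on top of an initial Poisson log-linear fit
#' with log-size-factor offsets: for each feature,
#' `alpha = max(sum(((k - mu)^2 - mu) / mu^2) / (n - p), alpha_min)` where
#' `mu` are the fitted Poisson means and `p` the number of design columns.
#' Features with all-zero counts are not fitted and return `NA`.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param design numeric design matrix (samples x coefficients), full rank.
#' @param size_factors positive per-sample factors.
#' @param alpha_min lower bound on the dispersion (default 1e-8).
#' @return named numeric vector of dispersions (`NA` for all-zero features).
#' @export
estimate_dispersion <- function(counts, design, size_factors, alpha_min = 1e-8) {
  check_count_matrix(counts)
  stopifnot(nrow(design) == ncol(counts), length(size_factors) == ncol(counts))
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  out <- rep(NA_real_, nrow(counts))
  names(out) <- rownames(counts)
  fit_idx <- rowSums(counts) > 0
  if (any(fit_idx)) {
    out[fit_idx] <- moment_dispersion_matrix(
      counts[fit_idx, , drop = FALSE], design, log(size_factors),
      alpha_min = alpha_min)
  }
  out
}

# internal: parse "EXAC:CTL" or c("EXAC","CTL")
parse_contrast <- function(contrast) {
  if (length(contrast) == 1) contrast <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(contrast) != 2 || contrast[1] == contrast[2])
    stop("contrast must name two distinct groups, e.g. c('EXAC','CTL') or 'EXAC:CTL'")
  contrast
}

#' Negative-binomial Wald test for one contrast
#'
#' A lightweight per-feature differential expression test for count data:
#' samples are restricted to the contrast's two groups; a log-link NB GLM
#' (intercept + group + covariates, log-size-factor offsets, per-feature
#' method-of-moments dispersion) is fitted by IRLS, and a two-sided Wald
#' p-value is computed for the group coefficient. The Wald statistic is
#' referred to a t distribution with `n - p` residual degrees of freedom
#' rather than the standard normal: with the dispersion estimated from the
#' same few samples, normal tails are anti-conservative at these sample
#' sizes and destroy false-discovery-rate control. P-values are
#' Benjamini-Hochberg adjusted over all tested, converged features. No
#' dispersion or fold-change shrinkage and no independent filtering are
#' applied.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param samples data.frame with columns `sample_id`, `group` and any
#'   covariate columns; one row per count-matrix sample.
#' @param contrast two group labels, numerator first, as a length-2 vector
#'   or a `"NUM:DEN"` string.
#' @param covariates character vector of sample-sheet columns to adjust for
#'   (default `c("sex", "batch")`; columns absent from the sheet or constant
#'   within the contrast are dropped).
#' @param size_factors optional per-sample factors for the full matrix;
#'   computed from the full matrix by default.
#' @param alpha_min dispersion lower bound passed to
#'   [estimate_dispersion()].
#' @return data.frame with one row per feature: `feature_id`, `base_mean`
#'   (mean normalized count over the contrast's samples), `log2fc`, `se`,
#'   `stat`, `pvalue`, `padj`, `tested`, `converged`. Features with all-zero
#'   counts are untested and carry `NA` statistics; non-convergent features
#'   are excluded from the adjustment.
#' @export
wald_test <- function(counts, samples, contrast,
                      covariates = c("sex", "batch"),
                      size_factors = NULL, alpha_min = 1e-8) {
  check_count_matrix(counts)
  check_sample_sheet(samples, counts)
  contrast <- parse_contrast(contrast)
  if (!all(contrast %in% samples$group))
    stop("both contrast groups must be present in the sample sheet")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)

  covariates <- intersect(covariates, names(samples))
  keep <- samples$group %in% contrast
  sub_samples <- samples[keep, , drop = FALSE]
  sub_counts <- counts[, sub_samples$sample_id, drop = FALSE]
  sub_sf <- size_factors[sub_samples$sample_id]

  X <- build_design(sub_samples, contrast, covariates)
  grp_col <- grep("^group", colnames(X))
  stopifnot(length(grp_col) == 1)

  norm <- sweep(sub_counts, 2, sub_sf, "/")
  res <- data.frame(
    feature_id = rownames(counts),
    base_mean = rowMeans(norm),
    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
    pvalue = NA_real_, padj = NA_real_,
    tested = rowSums(sub_counts) > 0,
    converged = NA,
    row.names = NULL, stringsAsFactors = FALSE)

  idx <- which(res$tested)
  if (length(idx)) {
    disp <- estimate_dispersion(sub_counts[idx, , drop = FALSE], X, sub_sf,
                                alpha_min = alpha_min)
    fit <- nb_glm_fit_matrix(sub_counts[idx, , drop = FALSE], X, log(sub_sf),
                             disp, tol = 1e-8, maxit = 100)
    res$converged[idx] <- fit$converged
    beta <- fit$beta[, grp_col]
    se <- fit$se[, grp_col]
    res$log2fc[idx] <- beta / log(2)
    res$se[idx] <- se / log(2)
    stat <- beta / se
    res$stat[idx] <- stat
    pv <- 2 * pt(-abs(stat), df = nrow(X) - ncol(X))
    ok <- fit$converged & is.finite(pv)
    res$pvalue[idx[ok]] <- pv[ok]
    res$padj[idx[ok]] <- bh_adjust(pv[ok])
  }
  attr(res, "contrast") <- contrast
  attr(res, "design_columns") <- colnames(X)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: with the inputs sorted ascending,
#' `q_i = min over k >= i of p_k * m / k`, capped at 1, then restored to the
#' input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; missing values
#'   are an error.
#' @return numeric vector of adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values)) stop("p-values must not be missing")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  q <- rev(cummin(rev(p_values[ord] * m / seq_len(m))))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

#' Select significant features
#'
#' Features whose BH-adjusted p-value is at or below the threshold
#' (inclusive).
#'
#' @param results a [wald_test()] result table.
#' @param alpha significance threshold on `padj` (default 0.05).
#' @return character vector of significant `feature_id`s.
#' @export
select_significant <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), "padj" %in% names(results))
  results$feature_id[!is.na(results$padj) & results$padj <= alpha]
}
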