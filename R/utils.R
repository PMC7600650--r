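#' Round half away from zero
#'
#' Fixed-precision rounding where ties at the half are moved away from zero,
#' the convention used when reporting correlation summaries (e.g. -0.775
#' becomes -0.78). Base `round()` rounds half to even, which differs at the
#' boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by a relative epsilon so values that are exactly representable
  # halves (0.775 * 100 = 77.49999...) land on the intended side
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Identify provisional (novel) miRNA identifiers
#'
#' Novel miRNA candidates discovered from read data carry provisional
#' identifiers built from their genomic origin (a chromosome or scaffold
#' name plus an index, e.g. `eca-miR-chrX_37753` or
#' `eca-miR-NW_019643269.1_38788`), in contrast to annotated mature miRNA
#' names such as `eca-miR-142-3p`.
#'
#' @param ids character vector of miRNA identifiers.
#' @return logical vector, `TRUE` where the identifier is provisional.
#' @export
is_provisional_mirna <- function(ids) {
  grepl("(chr[0-9XYMUn]+_|NW_|NC_|scaffold)", ids, ignore.case = FALSE)
}

#' Map miRNA identifiers to the human namespace
#'
#' Interaction databases index targets by human miRNA names. Annotated
#' equine miRNAs share names with their human counterparts up to the species
#' prefix, so the default mapping replaces a leading species prefix
#' (e.g. `eca-`) with `hsa-`. An explicit override table takes precedence.
#' Provisional identifiers have no homolog namespace and map to `NA`.
#'
#' @param ids character vector of miRNA identifiers.
#' @param override optional data.frame with columns `from`, `to` applied
#'   before the prefix rule.
#' @return character vector of mapped identifiers (`NA` where unmappable).
#' @export
map_mirna_ids <- function(ids, override = NULL) {
  out <- ids
  mapped <- rep(FALSE, length(ids))
  if (!is.null(override)) {
    stopifnot(all(c("from", "to") %in% names(override)))
    hit <- match(out, override$from)
    mapped <- !is.na(hit)
    out[mapped] <- override$to[hit[mapped]]
  }
  out[!mapped] <- sub("^[a-z]{3}-", "hsa-", out[!mapped])
  out[is_provisional_mirna(ids) & !mapped] <- NA_character_
  out
}

# internal: validate a counts matrix (integer-valued, non-negative, labelled)
check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature and sample names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("feature and sample names must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  invisible(counts)
}

# internal: validate a sample sheet against a counts matrix
check_sample_sheet <- function(samples, counts = NULL) {
  req <- c("sample_id", "group")
  if (!all(req %in% names(samples))) stop("sample sheet needs sample_id and group")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), samples$sample_id))
      stop("sample sheet and count matrix samples disagree")
  }
  invisible(samples)
}
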