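#' Canonicalize an RNA sequence
#'
#' Lowercases the sequence and converts T to U; any character outside
#' a, c, g, u is an error.
#'
#' @param sequence a single sequence string.
#' @return canonical lowercase RNA string.
#' @export
normalize_rna <- function(sequence) {
  s <- chartr("T", "U", toupper(sequence))
  s <- tolower(s)
  if (grepl("[^acgu]", s)) stop("sequence contains non-RNA characters: ", sequence)
  s
}

#' Extract the miRNA seed
#'
#' The seed region of a mature miRNA: nucleotides 2 to 8 from the 5' end
#' (1-based), the primary determinant of target recognition and the basis
#' of seed-identity homolog classification.
#'
#' @param sequence mature miRNA sequence of length >= 8 (RNA or DNA
#'   alphabet; canonicalized internally).
#' @return the 7-nucleotide seed as lowercase RNA.
#' @export
extract_seed <- function(sequence) {
  s <- normalize_rna(sequence)
  if (nchar(s) < 8) stop("sequence shorter than 8 nt has no seed")
  substr(s, 2, 8)
}

#' End-gap-free alignment identity between two short sequences
#'
#' Semi-global (overlap) alignment with match +1, mismatch 0 and internal
#' gap -2; leading and trailing gaps are free and excluded from the aligned
#' region. Identity is the fraction of matching columns among aligned
#' columns; the mismatch count is the number of aligned non-matching
#' columns plus internal gap columns. Traceback ties prefer diagonal, then
#' the gap in the subject, so results are deterministic.
#'
#' @param query,subject sequence strings (canonicalized internally).
#' @return list with `identity`, `mismatches`, `matches`,
#'   `aligned_length`, and the alignment `score`.
#' @export
align_identity <- function(query, subject) {
  qs <- normalize_rna(query)
  ss <- normalize_rna(subject)
  # canonical orientation: identity, matches and gap counts are symmetric
  # under swapping, so resolving traceback ties on a fixed ordering makes
  # the reported alignment statistics exactly symmetric as well
  if (qs > ss) { tmp <- qs; qs <- ss; ss <- tmp }
  a <- strsplit(qs, "")[[1]]
  b <- strsplit(ss, "")[[1]]
  n <- length(a)
  m <- length(b)
  gap <- -2
  S <- matrix(0, n + 1, m + 1)  # free end gaps: first row/column stay 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag <- S[i, j] + as.integer(a[i] == b[j])
      S[i + 1, j + 1] <- max(diag, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  # best cell on the last row or column (free trailing gaps); ties prefer
  # larger i, then larger j, scanning deterministically
  best <- c(n + 1, m + 1)
  best_s <- S[n + 1, m + 1]
  for (j in seq_len(m + 1)) {
    if (S[n + 1, j] > best_s) { best_s <- S[n + 1, j]; best <- c(n + 1, j) }
  }
  for (i in seq_len(n + 1)) {
    if (S[i, m + 1] > best_s) { best_s <- S[i, m + 1]; best <- c(i, m + 1) }
  }
  i <- best[1]; j <- best[2]
  matches <- 0L; mismatches <- 0L; gaps <- 0L; cols <- 0L
  while (i > 1 && j > 1) {
    diag <- S[i - 1, j - 1] + as.integer(a[i - 1] == b[j - 1])
    if (S[i, j] == diag) {
      if (a[i - 1] == b[j - 1]) matches <- matches + 1L else mismatches <- mismatches + 1L
      i <- i - 1; j <- j - 1
    } else if (S[i, j] == S[i - 1, j] + gap) {
      gaps <- gaps + 1L
      i <- i - 1
    } else {
      gaps <- gaps + 1L
      j <- j - 1
    }
    cols <- cols + 1L
  }
  list(identity = if (cols > 0) matches / cols else 0,
       mismatches = mismatches + gaps,
       matches = matches,
       aligned_length = cols,
       score = best_s)
}

#' Classify a novel miRNA against a reference set
#'
#' Finds the reference mature miRNA with the highest alignment identity
#' (ties broken by match count, then lexicographic identifier) and assigns
#' a class: `homolog` when the 7-nt seeds are identical and identity
#' reaches the threshold, `seed_only` when the seeds are identical but
#' identity falls short, and `none` otherwise or when the reference set is
#' empty.
#'
#' @param query_id identifier of the query miRNA.
#' @param query_seq mature query sequence.
#' @param references named character vector of reference mature sequences.
#' @param threshold homolog identity threshold in `[0, 1]` (default 0.90).
#' @return one-row data.frame: `query_id`, `subject_id`, `identity`,
#'   `mismatches`, `seed_identical`, `class`.
#' @export
classify_homolog <- function(query_id, query_seq, references,
                             threshold = 0.90) {
  none <- data.frame(query_id = query_id, subject_id = NA_character_,
                     identity = NA_real_, mismatches = NA_integer_,
                     seed_identical = NA, class = "none",
                     stringsAsFactors = FALSE)
  if (length(references) == 0) return(none)
  stopifnot(!is.null(names(references)))
  q_seed <- extract_seed(query_seq)
  hits <- lapply(references, function(ref) align_identity(query_seq, ref))
  identity <- vapply(hits, `[[`, numeric(1), "identity")
  matches <- vapply(hits, `[[`, numeric(1), "matches")
  ord <- order(-identity, -matches, names(references))
  best <- ord[1]
  subj <- names(references)[best]
  seed_ok <- nchar(references[[best]]) >= 8 &&
    extract_seed(references[[best]]) == q_seed
  cls <- if (seed_ok && identity[best] >= threshold) "homolog"
         else if (seed_ok) "seed_only" else "none"
  data.frame(query_id = query_id, subject_id = subj,
             identity = identity[best],
             mismatches = hits[[best]]$mismatches,
             seed_identical = seed_ok, class = cls,
             stringsAsFactors = FALSE)
}

#' Classify a set of novel miRNAs
#'
#' Vectorized driver over [classify_homolog()].
#'
#' @param queries named character vector of query mature sequences.
#' @param references named character vector of reference mature sequences.
#' @param threshold homolog identity threshold (default 0.90).
#' @return data.frame with one row per query.
#' @export
classify_homologs <- function(queries, references, threshold = 0.90) {
  stopifnot(!is.null(names(queries)))
  out <- do.call(rbind, lapply(names(queries), function(id)
    classify_homolog(id, queries[[id]], references, threshold)))
  rownames(out) <- NULL
  out
}
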