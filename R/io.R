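#' Read a feature-by-sample count matrix from TSV
#'
#' Expects a tab-separated file whose first column, `feature_id`, holds
#' unique feature names and whose remaining columns are samples with
#' integer counts.
#'
#' @param path file path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") stop("first column must be feature_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$feature_id
  check_count_matrix(m)
}

#' Write a count matrix to TSV
#'
#' @param counts integer matrix with dimnames.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  check_count_matrix(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `group` (e.g. EXAC / REM / CTL) and optionally
#' covariates such as `sex` and `batch`.
#'
#' @param path file path.
#' @return data.frame of sample annotations.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_sample_sheet(df)
  df
}

#' Read a miRNA-gene interaction table from TSV
#'
#' Columns: `mirna_id` (human namespace), `gene_id`, `db_name`. Duplicate
#' (miRNA, gene) rows within one database are an error.
#'
#' @param path file path.
#' @return data.frame with the three columns above.
#' @export
read_interactions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("mirna_id", "gene_id", "db_name")
  if (!all(req %in% names(df))) stop("interaction table needs ", paste(req, collapse = ", "))
  if (anyDuplicated(df[, req]))
    stop("duplicate (mirna, gene) rows within one database")
  df[, req]
}

#' Read mature miRNA sequences from FASTA
#'
#' Sequences are canonicalized to lowercase RNA (T is accepted on input and
#' normalized to U).
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return named character vector of RNA sequences.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), normalize_rna, character(1))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a synthetic dataset to a directory
#'
#' Emits `mirna_counts.tsv`, `mrna_counts.tsv`, `samples.tsv`, `truth.json`
#' and one `interactions_<db>.tsv` per interaction database; the tabular
#' files round-trip losslessly through the package readers.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir destination directory (created if absent).
#' @return data.frame manifest with columns `file`, `type`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  manifest <- data.frame(file = character(0), type = character(0))
  add <- function(file, type) rbind(manifest, data.frame(file = file, type = type))

  write_counts(dataset$mirna_counts, file.path(dir, "mirna_counts.tsv"))
  manifest <- add("mirna_counts.tsv", "counts")
  write_counts(dataset$mrna_counts, file.path(dir, "mrna_counts.tsv"))
  manifest <- add("mrna_counts.tsv", "counts")
  write.table(dataset$samples, file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- add("samples.tsv", "samples")
  for (db in names(dataset$interactions)) {
    f <- paste0("interactions_", db, ".tsv")
    write.table(dataset$interactions[[db]], file.path(dir, f),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- add(f, "interactions")
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- add("truth.json", "truth")
  manifest
}

#' Read a synthetic dataset back from a directory
#'
#' Counterpart of [write_dataset()].
#'
#' @param dir directory written by [write_dataset()].
#' @return list with `mirna_counts`, `mrna_counts`, `samples`,
#'   `interactions`, `truth`.
#' @export
read_dataset <- function(dir) {
  files <- list.files(dir)
  inter_files <- sort(grep("^interactions_.*\\.tsv$", files, value = TRUE))
  interactions <- lapply(file.path(dir, inter_files), read_interactions)
  names(interactions) <- sub("^interactions_(.*)\\.tsv$", "\\1", inter_files)
  list(
    mirna_counts = read_counts(file.path(dir, "mirna_counts.tsv")),
    mrna_counts = read_counts(file.path(dir, "mrna_counts.tsv")),
    samples = read_sample_sheet(file.path(dir, "samples.tsv")),
    interactions = interactions,
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE))
}
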