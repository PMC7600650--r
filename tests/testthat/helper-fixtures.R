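# small deterministic fixtures shared across test files

# tiny labelled count matrix
toy_counts <- function(values, n_feat, n_samp, prefix = "F") {
  m <- matrix(as.integer(values), n_feat, n_samp)
  rownames(m) <- sprintf("%s%02d", prefix, seq_len(n_feat))
  colnames(m) <- sprintf("S%02d", seq_len(n_samp))
  m
}

# two-group sample sheet without covariates
toy_samples <- function(n_per_group, groups = c("EXAC", "CTL")) {
  n <- n_per_group * length(groups)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             group = rep(groups, each = n_per_group),
             stringsAsFactors = FALSE)
}

# independent brute-force BH step-up: literal definition, quadratic scan
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# independent memoised recursion for the end-gap-free alignment score
# (match +1, mismatch 0, internal gap -2, free end gaps)
overlap_score_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- max(rec(i - 1, j - 1) + (a[i] == b[j]),
             rec(i - 1, j) - 2,
             rec(i, j - 1) - 2)
    memo[[key]] <- v
    v
  }
  best <- 0
  for (i in 0:length(a)) best <- max(best, rec(i, length(b)))
  for (j in 0:length(b)) best <- max(best, rec(length(a), j))
  best
}

random_rna <- function(n) paste(sample(c("a", "c", "g", "u"), n, replace = TRUE),
                                collapse = "")
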