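#' Simulation configuration
#'
#' Parameters of the synthetic miRNA/mRNA count generator. Defaults emulate
#' the lung-tissue study design the pipeline was built around: three cohorts
#' (exacerbation, remission, control) of sizes 6 / 5 / 8, sex and RNA
#' extraction batch as covariates, negative-binomial counts with log-normal
#' feature baselines, planted per-contrast log2 fold changes, and planted
#' multiplicative miRNA-to-gene repression that induces negative expression
#' correlation between paired features.
#'
#' @param n_mirna,n_gene numbers of miRNA and mRNA features.
#' @param group_sizes three positive integers, samples per group
#'   (EXAC, REM, CTL).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters (natural
#'   log) of the per-feature baseline mean expression.
#' @param dispersion_range interval the per-feature NB dispersion is drawn
#'   uniformly from; lower bound must be positive.
#' @param de_fraction fraction of features given a nonzero group effect,
#'   independently for the exacerbation and remission groups (control is
#'   the reference).
#' @param de_log2fc_range interval of planted |log2 fold change| magnitudes;
#'   signs are random.
#' @param n_regulatory_pairs number of planted miRNA-gene repression pairs.
#'   Pair miRNAs are drawn from the annotated (non-provisional) miRNAs and
#'   forced to be differentially expressed in the exacerbation group; pair
#'   genes are drawn, without replacement, from genes with no planted effect
#'   of their own.
#' @param repression_strength_gamma exponent of the repression: the paired
#'   gene's expected mean in sample `j` is scaled by
#'   `(m_j / mean(m))^(-gamma)` where `m_j` is the miRNA's expected
#'   normalized abundance.
#' @param n_decoy_interactions interaction-table rows sampled uniformly,
#'   without replacement, from non-planted (annotated miRNA, gene)
#'   combinations.
#' @param n_databases number of interaction tables; every planted pair is
#'   listed in at least one.
#' @param frac_novel_mirna fraction of miRNAs given provisional
#'   (novel-style) identifiers; these never enter interaction tables.
#' @param covariate_log2_sd standard deviation of per-feature sex and batch
#'   effects (log2 scale).
#' @param biological_log2_sd standard deviation of the per-sample,
#'   per-feature biological fluctuation of the expected mean (log2 scale);
#'   the repression tracks these fluctuations, so planted pairs correlate
#'   within groups and not only through group shifts.
#' @param libsize_log_sd standard deviation (natural log) of the per-sample
#'   library-depth factor, drawn separately for the two matrices.
#' @param seed integer RNG seed; the whole dataset is deterministic given
#'   the configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mirna = 50, n_gene = 200,
                       group_sizes = c(EXAC = 6, REM = 5, CTL = 8),
                       baseline_log_mean = log(100), baseline_log_sd = 1.5,
                       dispersion_range = c(0.05, 0.5),
                       de_fraction = 0.1, de_log2fc_range = c(1, 3),
                       n_regulatory_pairs = 20,
                       repression_strength_gamma = 1.5,
                       n_decoy_interactions = 200, n_databases = 4,
                       frac_novel_mirna = 0.2,
                       covariate_log2_sd = 0.2,
                       biological_log2_sd = 0.7,
                       libsize_log_sd = 0.2,
                       seed = 1) {
  cfg <- list(n_mirna = n_mirna, n_gene = n_gene, group_sizes = group_sizes,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion_range = dispersion_range,
              de_fraction = de_fraction,
              de_log2fc_range = de_log2fc_range,
              n_regulatory_pairs = n_regulatory_pairs,
              repression_strength_gamma = repression_strength_gamma,
              n_decoy_interactions = n_decoy_interactions,
              n_databases = n_databases,
              frac_novel_mirna = frac_novel_mirna,
              covariate_log2_sd = covariate_log2_sd,
              biological_log2_sd = biological_log2_sd,
              libsize_log_sd = libsize_log_sd,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_mirna >= 1, cfg$n_gene >= 1)
  if (length(cfg$group_sizes) != 3 || any(cfg$group_sizes < 1))
    stop("group_sizes must be three positive integers")
  if (cfg$baseline_log_sd <= 0) stop("baseline_log_sd must be positive")
  if (length(cfg$dispersion_range) != 2 || cfg$dispersion_range[1] <= 0 ||
      diff(cfg$dispersion_range) < 0)
    stop("dispersion_range must be an increasing interval with positive lower bound")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (cfg$n_regulatory_pairs < 0 ||
      cfg$n_regulatory_pairs > cfg$n_mirna * cfg$n_gene)
    stop("n_regulatory_pairs must lie in [0, n_mirna * n_gene]")
  if (cfg$repression_strength_gamma < 0) stop("gamma must be non-negative")
  if (cfg$n_decoy_interactions < 0) stop("n_decoy_interactions must be non-negative")
  if (cfg$n_databases < 1) stop("n_databases must be positive")
  invisible(cfg)
}

# internal: round-robin covariate assignment within each group so that sex
# and batch vary within groups and the design stays full rank
make_sample_sheet <- function(group_sizes) {
  groups <- rep(c("EXAC", "REM", "CTL"), times = group_sizes)
  n <- length(groups)
  sex <- batch <- character(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    k <- seq_along(idx)
    sex[idx] <- c("F", "M")[(k - 1) %% 2 + 1]
    batch[idx] <- c("B1", "B1", "B2", "B2")[(k - 1) %% 4 + 1]
  }
  data.frame(sample_id = sprintf("S%02d", seq_len(n)), group = groups,
             sex = sex, batch = batch, stringsAsFactors = FALSE)
}

#' Draw negative-binomial counts for a mean matrix
#'
#' Independent NB draws with variance `mu + alpha * mu^2`, one dispersion
#' per feature (row). A mean of zero yields a count of zero.
#'
#' @param mean_matrix non-negative expected counts, features x samples.
#' @param dispersion positive per-feature dispersions (length 1 is
#'   recycled).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return integer count matrix with the dimnames of `mean_matrix`.
#' @export
sample_nb_counts <- function(mean_matrix, dispersion, seed = NULL) {
  if (any(mean_matrix < 0)) stop("means must be non-negative")
  if (any(dispersion <= 0)) stop("dispersions must be positive")
  if (length(dispersion) == 1) dispersion <- rep(dispersion, nrow(mean_matrix))
  if (length(dispersion) != nrow(mean_matrix))
    stop("need one dispersion per feature")
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(0L, nrow(mean_matrix), ncol(mean_matrix),
                   dimnames = dimnames(mean_matrix))
  for (i in seq_len(nrow(mean_matrix))) {
    counts[i, ] <- rnbinom(ncol(mean_matrix), mu = mean_matrix[i, ],
                           size = 1 / dispersion[i])
  }
  if (max(counts) > .Machine$integer.max)
    stop("simulated counts exceed integer range; lower the baseline means")
  storage.mode(counts) <- "integer"
  counts
}

# internal: log2 expected normalized abundance for one feature set
make_log2_mu <- function(log2_base, eff_exac, eff_rem, sex_eff, batch_eff,
                         samples, bio_sd) {
  nf <- length(log2_base)
  ns <- nrow(samples)
  eff <- cbind(EXAC = eff_exac, REM = eff_rem, CTL = 0)
  mu <- matrix(log2_base, nf, ns) +
    eff[, samples$group, drop = FALSE] +
    outer(sex_eff, as.numeric(samples$sex == "M")) +
    outer(batch_eff, as.numeric(samples$batch == "B2"))
  if (bio_sd > 0) mu <- mu + matrix(rnorm(nf * ns, 0, bio_sd), nf, ns)
  mu
}

#' Generate a synthetic miRNA/mRNA dataset
#'
#' Draws a complete, seeded dataset with the statistical structure the
#' analysis pipeline assumes: log-normal feature baselines, per-group
#' planted log2 fold changes (control as reference), sex/batch covariate
#' effects, per-sample biological fluctuations, planted miRNA-mediated
#' repression acting on expected means, NB counts with per-feature
#' dispersion, library-depth variation, and matching interaction tables
#' containing every planted pair plus uniform decoys.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_dataset`: a list with `mirna_counts`,
#'   `mrna_counts`, `samples`, `interactions` (one data.frame per
#'   database), `truth` (per-contrast planted DE features with true log2FC,
#'   and planted pairs with gamma) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  samples <- make_sample_sheet(config$group_sizes)
  ns <- nrow(samples)

  n_novel <- round(config$frac_novel_mirna * config$n_mirna)
  n_known <- config$n_mirna - n_novel
  if (n_known < 1 && config$n_regulatory_pairs > 0)
    stop("planted pairs require at least one annotated miRNA")
  mirna_ids <- c(sprintf("eca-miR-%d", 100 + seq_len(n_known)),
                 sprintf("eca-miR-chr%d_%d", (seq_len(n_novel) - 1) %% 31 + 1,
                         30000 + seq_len(n_novel)))
  known_ids <- mirna_ids[seq_len(n_known)]
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_gene))

  draw_features <- function(n) {
    list(base = log2(rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)),
         disp = runif(n, config$dispersion_range[1], config$dispersion_range[2]),
         eff_exac = planted_effects(n, config),
         eff_rem = planted_effects(n, config),
         sex_eff = rnorm(n, 0, config$covariate_log2_sd),
         batch_eff = rnorm(n, 0, config$covariate_log2_sd))
  }
  mi <- draw_features(config$n_mirna)
  mg <- draw_features(config$n_gene)

  # planted repression pairs: miRNA side annotated and DE in exacerbation,
  # gene side free of planted effects of its own
  pairs <- data.frame(mirna_id = character(0), gene_id = character(0),
                      gamma = numeric(0), stringsAsFactors = FALSE)
  if (config$n_regulatory_pairs > 0) {
    pm <- sample(seq_len(n_known), config$n_regulatory_pairs,
                 replace = config$n_regulatory_pairs > n_known)
    need <- mi$eff_exac[pm] == 0
    mi$eff_exac[pm[need]] <- draw_lfc(sum(need), config)
    free_genes <- which(mg$eff_exac == 0 & mg$eff_rem == 0)
    if (length(free_genes) < config$n_regulatory_pairs)
      stop("not enough effect-free genes to host the planted pairs")
    pg <- sample(free_genes, config$n_regulatory_pairs)
    pairs <- data.frame(mirna_id = mirna_ids[pm], gene_id = gene_ids[pg],
                        gamma = config$repression_strength_gamma,
                        stringsAsFactors = FALSE)
  }

  log2_mu_mi <- make_log2_mu(mi$base, mi$eff_exac, mi$eff_rem, mi$sex_eff,
                             mi$batch_eff, samples, config$biological_log2_sd)
  log2_mu_mg <- make_log2_mu(mg$base, mg$eff_exac, mg$eff_rem, mg$sex_eff,
                             mg$batch_eff, samples, config$biological_log2_sd)
  rownames(log2_mu_mi) <- mirna_ids
  rownames(log2_mu_mg) <- gene_ids

  gamma <- config$repression_strength_gamma
  for (i in seq_len(nrow(pairs))) {
    m <- 2^log2_mu_mi[pairs$mirna_id[i], ]
    log2_mu_mg[pairs$gene_id[i], ] <-
      log2_mu_mg[pairs$gene_id[i], ] - gamma * log2(m / mean(m))
  }

  lib_mi <- exp(rnorm(ns, 0, config$libsize_log_sd))
  lib_mg <- exp(rnorm(ns, 0, config$libsize_log_sd))
  mu_mi <- sweep(2^log2_mu_mi, 2, lib_mi, "*")
  mu_mg <- sweep(2^log2_mu_mg, 2, lib_mg, "*")
  colnames(mu_mi) <- colnames(mu_mg) <- samples$sample_id
  mirna_counts <- sample_nb_counts(mu_mi, mi$disp)
  mrna_counts <- sample_nb_counts(mu_mg, mg$disp)

  truth <- list(
    de = truth_de_tables(mirna_ids, gene_ids, mi, mg, pairs, gamma),
    pairs = pairs,
    group_sizes = as.integer(config$group_sizes),
    seed = config$seed)

  interactions <- make_interaction_tables(pairs, known_ids, gene_ids, config)

  structure(list(mirna_counts = mirna_counts, mrna_counts = mrna_counts,
                 samples = samples, interactions = interactions,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}

# internal: nonzero log2 effects for a de_fraction of features
planted_effects <- function(n, config) {
  eff <- numeric(n)
  hit <- runif(n) < config$de_fraction
  eff[hit] <- draw_lfc(sum(hit), config)
  eff
}

draw_lfc <- function(n, config) {
  if (n == 0) return(numeric(0))
  mag <- runif(n, config$de_log2fc_range[1], config$de_log2fc_range[2])
  mag * sample(c(-1, 1), n, replace = TRUE)
}

# internal: per-contrast truth tables; a planted pair makes its gene DE in
# every contrast where the miRNA is, with induced log2FC -gamma * lfc_mirna
truth_de_tables <- function(mirna_ids, gene_ids, mi, mg, pairs, gamma) {
  contrasts <- list(`EXAC:CTL` = c("EXAC", "CTL"),
                    `REM:CTL` = c("REM", "CTL"),
                    `EXAC:REM` = c("EXAC", "REM"))
  eff_of <- function(feat, grp) {
    if (grp == "CTL") return(numeric(length(feat$base)))
    if (grp == "EXAC") feat$eff_exac else feat$eff_rem
  }
  out <- lapply(contrasts, function(ct) {
    lfc_mi <- eff_of(mi, ct[1]) - eff_of(mi, ct[2])
    lfc_mg <- eff_of(mg, ct[1]) - eff_of(mg, ct[2])
    names(lfc_mi) <- mirna_ids
    names(lfc_mg) <- gene_ids
    induced <- -gamma * lfc_mi[pairs$mirna_id]
    lfc_mg[pairs$gene_id] <- lfc_mg[pairs$gene_id] + induced
    de <- rbind(
      data.frame(feature_id = mirna_ids[lfc_mi != 0],
                 kind = rep("miRNA", sum(lfc_mi != 0)),
                 log2fc = unname(lfc_mi[lfc_mi != 0]), stringsAsFactors = FALSE),
      data.frame(feature_id = gene_ids[lfc_mg != 0],
                 kind = rep("mRNA", sum(lfc_mg != 0)),
                 log2fc = unname(lfc_mg[lfc_mg != 0]), stringsAsFactors = FALSE))
    rownames(de) <- NULL
    de
  })
  names(out) <- names(contrasts)
  out
}

# internal: one interaction table per database, human miRNA namespace;
# every planted pair is listed in >= 1 database, decoys are uniform draws
# from the non-planted (annotated miRNA, gene) grid without replacement
make_interaction_tables <- function(pairs, known_ids, gene_ids, config) {
  ndb <- config$n_databases
  db_names <- sprintf("db%d", seq_len(ndb))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    in_db <- runif(ndb) < 0.5
    if (!any(in_db)) in_db[sample.int(ndb, 1)] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      mirna_id = map_mirna_ids(pairs$mirna_id[i]),
      gene_id = pairs$gene_id[i], db_name = db_names[in_db],
      stringsAsFactors = FALSE)
  }
  if (config$n_decoy_interactions > 0) {
    grid_n <- length(known_ids) * length(gene_ids)
    planted_idx <- (match(pairs$gene_id, gene_ids) - 1) * length(known_ids) +
      match(pairs$mirna_id, known_ids)
    pool <- setdiff(seq_len(grid_n), planted_idx)
    if (config$n_decoy_interactions > length(pool))
      stop("not enough non-planted combinations for the requested decoys")
    decoy <- sample(pool, config$n_decoy_interactions)
    mi_idx <- (decoy - 1) %% length(known_ids) + 1
    g_idx <- (decoy - 1) %/% length(known_ids) + 1
    rows[[length(rows) + 1]] <- data.frame(
      mirna_id = map_mirna_ids(known_ids[mi_idx]),
      gene_id = gene_ids[g_idx],
      db_name = db_names[sample.int(ndb, length(decoy), replace = TRUE)],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(structure(list(), names = character(0)))
  all_rows <- do.call(rbind, rows)
  out <- lapply(db_names, function(db) {
    tab <- all_rows[all_rows$db_name == db, , drop = FALSE]
    tab <- tab[order(tab$mirna_id, tab$gene_id), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
  names(out) <- db_names
  out
}
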