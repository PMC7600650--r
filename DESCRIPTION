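Package: mirmint
Title: Integrative miRNA-mRNA Negative-Correlation Analysis for Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative small-RNA / mRNA expression analysis pipeline for
    multi-group count data: median-of-ratios normalization, a lightweight
    negative-binomial Wald test for per-contrast differential expression with
    categorical covariates, screening of differentially expressed miRNA-gene
    pairs for significant negative Pearson correlation with interaction-database
    support, bipartite miRNA-target regulatory networks with degree-based hub
    ranking, cross-contrast overlap analysis, and seed-based homolog
    classification of novel mature miRNA sequences. A seeded synthetic-data
    generator with planted fold changes and planted miRNA-mediated repression
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
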