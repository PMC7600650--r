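---
title: "mirmint: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirmint: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirmint` implements an integrative miRNA–mRNA expression analysis for a
three-cohort design (disease exacerbation, disease remission, healthy
controls, abbreviated EXAC / REM / CTL throughout): per-contrast
differential expression of miRNAs and mRNAs from count matrices, a screen
for differentially expressed miRNA–gene pairs with significantly negative
expression correlation and interaction-database support, bipartite
regulatory networks, cross-contrast overlap analysis, and seed-based
homolog classification of novel mature miRNAs. This vignette records the
models, the tunable parameters, and the design decisions that were
genuinely open, so that a user can judge what the package's tests do and do
not establish.

## Differential expression model

Counts for feature $i$ in sample $j$ are modelled as negative binomial,
$k_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\mathrm{Var}(k) = \mu + \alpha\mu^2$, and
$\log \mu_{ij} = x_j^\top\beta_i + \log s_j$, where $s_j$ are
median-of-ratios size factors and $x_j$ encodes an intercept, the contrast
group, and the categorical covariates (sex and RNA-extraction batch by
default; covariates that are constant within a contrast's samples are
dropped). Each contrast is fitted on the samples of its two groups only,
with the denominator group as reference level, so the group coefficient is
directly $\ln(\mu_\text{num}/\mu_\text{den})$ and
$\log_2\mathrm{FC} = \hat\beta_\text{group}/\ln 2$.

Dispersions are per-feature method-of-moments estimates on the residuals
of an initial Poisson fit,
$\hat\alpha_i = \max\!\big(\sum_j [((k_{ij}-\hat\mu_{ij})^2 -
\hat\mu_{ij})/\hat\mu_{ij}^2] / (n-p),\ 10^{-8}\big)$,
where $p$ is the number of design columns. There is no dispersion
shrinkage, no fold-change shrinkage, no independent filtering and no
outlier refitting: the test is deliberately a minimal, transparent NB Wald
test, not a re-implementation of any specific published tool.

**Reference distribution.** The Wald statistic is compared to a
$t_{n-p}$ distribution, not the standard normal. This is the one place
where the implementation departs from the most naive construction, and it
is essential: the plug-in dispersion is estimated from roughly a dozen
residual degrees of freedom, so the statistic's tails are much heavier
than normal. In global-null simulations (2,000 features, 8 vs 8 samples,
50 replicates — the sizes used by the test suite) the normal reference
produces at least one Benjamini–Hochberg discovery in almost every
replicate, while the $t_{n-p}$ reference keeps the raw
$p \le 0.05$ fraction near nominal and the realized false-discovery
proportion of BH-selected features below 5%. Small-sample count methods
that avoid shrinkage commonly make the same choice.

Features with all-zero counts in the contrast's samples are flagged
untested and excluded from the BH family; non-convergent IRLS fits
(tolerance $10^{-8}$ on the coefficients, at most 100 iterations,
linear-predictor clamped at $\pm 30$ to survive all-zero groups) are
reported with a convergence flag and likewise excluded from adjustment.
The significance call `padj <= alpha` is inclusive, with
$\alpha = 0.05$ by default.

Two smaller numerical conventions: the median over an even number of
ratios in the size-factor estimator is the arithmetic mean of the two
central ratios (so it is a true median on the ratio scale, which differs
in the fourth decimal from taking the median on the log scale), and the
log2 expression transform uses a configurable pseudocount of 1.

## The correlation screen

For one contrast, every pair of a significantly DE annotated miRNA with a
significantly DE gene is a candidate; provisional (novel) miRNA
identifiers are excluded before pairing because interaction databases
cannot support them. The Pearson coefficient is computed on the log2
normalized expression over the contrast's samples (configurable to all
samples), the two-sided p-value comes from the exact
$t = r\sqrt{(n-2)/(1-r^2)}$ null distribution, and BH adjustment runs
over the complete candidate family of that contrast — not only over the
pairs that end up supported. Pairs are retained when $r < 0$,
$p_\text{adj} \le 0.05$ (inclusive), and the interaction appears in at
least one supplied database after mapping the miRNA identifier to the
human namespace (species prefix replaced by `hsa-`, with an optional
user override table; gene symbols match case-insensitively). A pair with
a constant expression vector has no defined correlation and is dropped
from the family rather than raising an error. Output ordering is
deterministic: adjusted p-value, then $r$, then identifiers.

Whether the original analysis correlated over the contrast's two cohorts
or over all samples is not recoverable from the description it gives; both
are supported, the per-contrast restriction is the default, and the
packaged recovery benchmark uses all samples (below).

Summaries report the arithmetic mean and the $n-1$ standard deviation of
the retained coefficients, rounded half away from zero to two decimals for
reporting (the unrounded values are kept). Half-away rounding matters at
the boundary: four coefficients averaging exactly $-0.775$ report as
$-0.78$.

## Networks and homology

The per-contrast network contains one edge per (miRNA, gene, database)
triple whose miRNA and gene are both DE — parallel edges per supporting
database rather than weighted single edges, because both the edge
multiplicity and the distinct-partner count are biologically meaningful
and published figures are ambiguous between the two; `node_degrees()`
therefore reports both. Bipartiteness is asserted on every constructed
network. GraphML round-trips the graph with its attributes.

Novel-miRNA classification uses the seed (nucleotides 2–8 from the 5'
end) plus a percent identity from an end-gap-free (overlap) alignment
scoring match $+1$, mismatch $0$, internal gap $-2$; identity is
matches over aligned columns, excluding free end gaps, and the mismatch
count includes internal gaps. The published percent identities this
mirrors were produced by an unstated alignment scheme with an unknown
denominator, so this module defines its own scheme and makes no claim of
reproducing those exact percentages. Classes: `homolog` when the seeds
are identical and identity reaches the threshold (default 0.90, the
level at which the published homolog assignments and seed-only
assignments separate), `seed_only` when only the seed matches, `none`
otherwise. Tie-breaks (best subject by identity, then match count, then
identifier; alignment traceback on a canonicalized orientation) make the
classification deterministic and symmetric.

## The synthetic-data generator

`generate_dataset()` draws a complete dataset the pipeline can run on:
log-normal per-feature baselines (default $e^{\mathcal N(\ln 100, 1.5^2)}$,
spanning the count range from tens to hundreds of thousands seen in small
RNA libraries); uniform per-feature NB dispersions on $[0.05, 0.5]$;
group sizes 6/5/8 matching the cohort sizes of the motivating study (its
own reporting is internally inconsistent between six and seven exacerbated
animals; the results-section count of six is used, and the sizes are
configurable); sex and batch assigned round-robin within groups so the
covariate design is always estimable; per-feature covariate effects of sd
0.2 log2 units; per-sample library-depth factors of sd 0.2 on the natural
log scale; a `de_fraction` (default 0.1) of features given planted log2
effects of magnitude 1–3 with random signs, independently for the EXAC and
REM groups against the CTL reference; and `n_regulatory_pairs` planted
repression pairs (default 20) in which the gene's expected mean in sample
$j$ is scaled by $(m_j/\bar m)^{-\gamma}$, $m_j$ being the miRNA's
expected normalized abundance and $\gamma = 1.5$ by default. Planted-pair
miRNAs are drawn from the annotated miRNAs and forced to be DE in
exacerbation; pair genes are drawn from features with no planted effect of
their own, so their differential expression is entirely induced
($\log_2\mathrm{FC} = -\gamma\,\log_2\mathrm{FC}_\text{miRNA}$, recorded
in the truth tables).

One term extends the minimal generative model: a per-sample, per-feature
biological fluctuation of the expected mean (log2 sd 0.7, configurable,
corresponding to a within-group biological CV of roughly 50–60%) that the
planted repression *tracks*. Without it, a planted pair's negative
correlation is carried solely by the group-mean shift — and then any decoy
interaction that happens to join two oppositely-signed DE features is
statistically indistinguishable from a planted pair, which would make
precision of pair recovery a coin flip rather than a property of the
method. With tracking, planted pairs correlate within groups as well,
which is exactly the signature the correlation screen is designed to
exploit.

Interaction fixtures list every planted pair in at least one of
`n_databases` (default 4) tables under human-namespace identifiers, plus
`n_decoy_interactions` (default 200) rows drawn uniformly without
replacement from the non-planted (annotated miRNA, gene) grid. A fraction
of miRNAs (default 0.2) carries provisional identifiers and never enters
the tables. Everything is deterministic given the seed.

What the generator does *not* emulate: read-level artifacts (adapters,
mapping multi-hits, miRNA isoforms), compositional coupling between
features, correlated dispersion–mean trends, batch-by-group confounding,
and regulation acting on realized rather than expected abundance
(repression on expected means keeps every planted effect analytically
checkable). Passing tests on this generator therefore demonstrate the
statistical machinery under a faithful NB world with planted structure;
they do not certify behaviour under the full messiness of real libraries.

## The packaged benchmarks and their honest limits

The test suite and `scripts/acceptance.R` size their simulations to run
on a single CPU in well under their time budgets: 2,000-feature null
datasets over 50 replicates for false-discovery calibration, 500-feature
effect-recovery runs, and ten-seed pair-recovery benchmarks.

*Null calibration* is evaluated on the minimal generative model (the
fluctuation term switched off), i.e. data that actually follow the NB
observation model the test assumes. Under that null the realized
false-discovery proportion of BH selection at $\alpha = 0.05$ averages
well under the target. With the fluctuation term on, the counts are an
NB–lognormal mixture, the plug-in NB test is misspecified, and its far
tail inflates by roughly a factor of two — enough to put an occasional
feature past the BH boundary in a 2,000-feature family. This is a known
limitation of unshrunk plug-in NB inference under extra-NB noise, and it
is the reason shrinkage estimators exist; reproducing them is outside
this package's scope.

*Pair recovery* runs the screen with the generator's true DE sets (so it
measures pair discovery, not DE power) over all 19 samples. Recall is
limited by planted pairs whose miRNA has a small fold change and a high
dispersion — their correlation lands near $-0.5$ and does not survive BH
in a family of several hundred candidates. Precision is limited by a
structural confound: a decoy interaction joining a strongly up-regulated
miRNA to a strongly down-regulated gene is *genuinely* negatively
correlated through the shared group structure, and no per-contrast
correlation screen can tell it from direct repression; at the packaged
decoy density this caps mean precision slightly below 0.9. The
database-support requirement is what keeps this confound in check (the
unfiltered screen retains on the order of a hundred group-driven pairs);
an orthogonal fix — regressing out the group means before correlating —
would change the estimand and is deliberately not the default. Running
the same benchmark with estimated instead of true DE sets mainly measures
DE power at $n = 14$ without shrinkage, which is why the benchmark fixes
the DE sets to truth.

## Defaults worth knowing

| parameter | default | where | why |
|---|---|---|---|
| `alpha_de`, `alpha_corr` | 0.05 (inclusive) | DE, screen | the conventional FDR level; inclusive per the motivating analysis |
| `pseudocount` | 1 | log2 expression | keeps zeros at 0 on the log2 scale |
| `alpha_min` | 1e-8 | dispersion | numerical floor, effectively Poisson |
| `homolog_threshold` | 0.90 | homology | separates published homolog from seed-only assignments |
| `correlation_samples` | `"contrast"` | screen | pairs are reported per contrast |
| `gamma` | 1.5 | generator | strong but not deterministic repression |
| `biological_log2_sd` | 0.7 | generator | within-group biological CV ~50–60% |
| `de_log2fc_range` | (1, 3) | generator | the range of published DE effect sizes |

## Reproducibility

Every stochastic component is driven by an explicit seed: the generator
embeds it in its config, the pipeline orders every output
deterministically, and identical configurations produce byte-identical
written bundles. `scripts/acceptance.R --seed S --out F` re-derives all
headline quantities from the installed package alone.
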