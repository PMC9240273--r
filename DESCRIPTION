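Package: viromemeta
Title: Multi-Cohort Gut Virome Case-Control Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control meta-analysis of gut virome shotgun
    profiles across multiple cohorts: majority-vote taxonomic assignment of
    phage genomes from ORF-level protein hits, trimmed-mean-of-M-values (TMM)
    count normalization, alpha-diversity statistics (Shannon, Heip evenness,
    Chao1) with naive and covariate-adjusted linear models,
    DerSimonian-Laird random-effects pooling of standardized mean differences
    and Fisher-z transformed correlations with Cochran's Q and I-squared
    heterogeneity, Bray-Curtis ordination (PCoA) and PERMANOVA, a two-group
    negative-binomial differential-abundance test with median-of-ratios size
    factors and Benjamini-Hochberg correction, pooled interkingdom
    (virus-bacterium) Spearman correlation grids, and a disease-status
    classification harness (within-study repeated cross-validation, pairwise
    cross-study transfer, and leave-one-dataset-out pooling, scored by AUROC).
    A synthetic multi-study cohort generator with known planted structure
    (between-study heterogeneity, batch offsets, differentially abundant
    taxa, cross-kingdom copula correlations) makes every stage testable
    end-to-end without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    metafor,
    vegan
Config/testthat/edition: 3
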