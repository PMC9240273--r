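# viromemeta

Case-control meta-analysis of the human gut **virome** across multiple
shotgun-metagenomic cohorts, for researchers studying disease-associated
shifts in the phage community (the motivating application is colorectal
cancer, CRC, versus healthy controls).

Published cohorts differ in country, protocol and sequencing depth, so no
single-study analysis is trustworthy on its own. This package implements
the full downstream statistical pipeline that such a comparison needs,
taking per-study taxa-by-samples count matrices (e.g. unique read mappings
against a phage genome catalogue), sample metadata, and ORF-level protein
hit tables as input:

* **Taxonomy by vote** — each phage genome is assigned family/genus/species
  by plurality vote over its ORFs' best protein hits (highest bit score,
  e-value cutoff); genomes with fewer than two classified ORFs, and tied
  votes, stay unclassified.
* **Normalization** — low-variance / low-prevalence taxon filtering and
  trimmed-mean-of-M-values (TMM) factors:
  $f_j = 2^{\sum_t w_t M_t / \sum_t w_t}$ over doubly-trimmed log-ratios,
  rescaled to geometric mean 1; abundances are CPM on the effective library.
* **Diversity** — Shannon $H = -\sum_i p_i \ln p_i$, Heip evenness
  $(e^H-1)/(S-1)$, Chao1 $S + f_1^2/2f_2$; per-study Wilcoxon tests and
  naive/covariate-adjusted linear models on $\ln(\text{diversity})$.
* **Random-effects meta-analysis** — Hedges-g standardized mean
  differences pooled by DerSimonian–Laird:
  $\hat\tau^2 = \max\!\big(0, (Q - df)/(\textstyle\sum w - \sum w^2/\sum w)\big)$,
  $\hat\mu = \sum y_i/(v_i+\hat\tau^2) \big/ \sum 1/(v_i+\hat\tau^2)$,
  with Cochran's Q and $I^2$ heterogeneity; Fisher-z pooling for
  correlations.
* **Ordination** — Bray–Curtis dissimilarity, principal coordinates
  analysis, and one-way PERMANOVA ($R^2$, pseudo-F, permutation p).
* **Differential abundance** — a two-group negative-binomial test with
  median-of-ratios size factors (exact conditional test at low counts,
  Welch-type Wald test otherwise), BH-FDR, and cross-study intersection
  counts.
* **Interkingdom correlations** — per-study Spearman grids between viral
  families and bacterial species, computed within disease group, pooled by
  Fisher-z random effects with BH masking.
* **Prediction harness** — within-study repeated stratified 10-fold CV,
  pairwise cross-study transfer, and leave-one-dataset-out (LODO)
  evaluation of a pluggable classifier (default: 1000-tree random forest),
  scored by AUROC.
* **Synthetic cohorts** — a generator that plants known structure
  (diversity effect sizes with between-study variance, fold changes,
  copula correlations, batch offsets) so every stage is testable with
  ground truth and no external data.

## Worked example

Three synthetic cohorts with a planted diversity effect (true SMD 0.4) and
three planted fold changes, then the diversity meta-analysis and one
study's differential-abundance test:

```r
library(viromemeta)

specs <- lapply(c("Helsinki", "Kyoto", "Austin"), function(id)
  cohort_spec(id, n_control = 30, n_case = 30, n_viral_taxa = 100,
              n_bacterial_taxa = 80, depth_mean = 5e4))
effects <- effect_spec(
  diversity_smd_mu = 0.4,
  da_taxa = data.frame(taxon_id = c("vsp050", "vsp065", "bsp040"),
                       log2fc = c(2, -2, 2)))
cohorts <- generate_cohort_set(specs, effects, seed = 42)

g <- lapply(names(cohorts$studies), function(id) {
  counts <- cohorts$studies[[id]]$viral
  md <- cohorts$metadata[cohorts$metadata$study == id, ]
  h <- apply(counts, 2, shannon)
  case <- md$group[match(colnames(counts), md$sample_id)] == "CRC"
  hedges_g(h[!case], h[case], label = id)
})
dl_pool(g)
#> Random-effects pooling (DerSimonian-Laird), k = 3 studies
#>   mu = 0.3828 (SE 0.1629), 95% CI [0.0635, 0.7020], z = 2.350, p = 0.0188
#>   tau2 = 0.0113, Q = 2.330 (df 2, p = 0.312), I2 = 14.1%
```

The pooled standardized mean difference (0.38, CI excluding zero) recovers
the planted 0.4: viral alpha diversity is higher in cases, consistently
across the three cohorts (low heterogeneity, I² = 14%). The planted fold
changes dominate one study's differential test:

```r
counts <- filter_taxa(cohorts$studies$Helsinki$viral)
da <- nb_test(counts,
              factor(cohorts$metadata$group[cohorts$metadata$study == "Helsinki"],
                     levels = c("control", "CRC")))
head(da[order(da$q), c("taxon", "log2fc", "p", "q")], 3)
#>     taxon    log2fc            p            q
#> 58 vsp065 -2.741190 3.346946e-14 1.974698e-12
#> 50 vsp050  2.331259 7.643706e-13 2.254893e-11
#> 1  vsp001 -0.505764 3.918141e-02 5.601001e-01
```

Both planted taxa surface with the right signs at tiny q-values; the next
candidate is already non-significant. `run_pipeline()` composes all stages
from a config list or YAML file and writes per-stage TSVs plus a JSON
summary; `inst/cli/virome-meta.R` is a thin command-line runner.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "viromemeta",
                               load_package = "installed")'
```

The suite includes closed-form oracles, brute-force references
(trim sets, pairwise AUROC concordance, exhaustive PERMANOVA
permutations), cross-checks against `edgeR`/`metafor`/`vegan`, and
planted-truth recovery simulations.

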