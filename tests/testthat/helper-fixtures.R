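# Shared fixture builders; everything is generated in code at test time.

# Small random count matrix with taxon/sample dimnames.
fixture_counts <- function(n_taxa = 30, n_samples = 8, mu = 50, size = 2,
                           seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_taxa * n_samples, mu = mu, size = size),
              n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

# Hit-table plan for a genome whose ORFs vote the given families.
plan_genome <- function(genome_id, families, bit = 100, evalue = 1e-20) {
  list(genome_id = genome_id,
       lineages = lapply(families, function(f)
         c(family = f, genus = paste0(f, "_g"), species = paste0(f, "_s"))),
       bit_scores = rep_len(bit, length(families)),
       e_values = rep_len(evalue, length(families)))
}

# Three-study synthetic cohort set used by several integration tests.
fixture_cohorts <- function(seed = 11, mu = 0.5, n = 30,
                            da = data.frame(
                              taxon_id = c("vsp040", "vsp055", "bsp030",
                                           "bsp045", "bsp021"),
                              log2fc = c(2, 2, 2, -2, 2)),
                            xk = NULL) {
  specs <- lapply(c("A", "B", "C"), function(id)
    cohort_spec(id, n, n, n_viral_taxa = 80, n_bacterial_taxa = 80,
                depth_mean = 2e4))
  generate_cohort_set(specs, effect_spec(diversity_smd_mu = mu,
                                         da_taxa = da,
                                         xk_correlations = xk), seed)
}
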