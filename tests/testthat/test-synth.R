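test_that("identical specs and seed reproduce identical cohorts", {
  a <- fixture_cohorts(seed = 5)
  b <- fixture_cohorts(seed = 5)
  expect_identical(a, b)
  c <- fixture_cohorts(seed = 6)
  expect_false(identical(a$studies$A$viral, c$studies$A$viral))
})

test_that("zero-taxon or tiny-arm specifications are rejected", {
  expect_error(cohort_spec("x", 1, 5), "n_control")
  expect_error(cohort_spec("x", 5, 5, n_viral_taxa = 0), "zero-taxon")
  expect_error(cohort_spec("x", 5, 5, depth_mean = 0), "depth_mean")
  expect_error(effect_spec(diversity_smd_tau2 = -1), "tau2")
  expect_error(effect_spec(xk_correlations = data.frame(
    viral_family = "vfam01", bacterial_species = "bsp001",
    rho_control = 1, rho_case = 0)), "rho")
})

test_that("realized library sizes track depth_mean within 5%", {
  cs <- generate_cohort_set(
    cohort_spec("big", 100, 100, n_viral_taxa = 100, n_bacterial_taxa = 50,
                depth_mean = 5e4),
    effect_spec(), seed = 2)
  expect_lt(abs(mean(colSums(cs$studies$big$viral)) / 5e4 - 1), 0.05)
  expect_lt(abs(mean(colSums(cs$studies$big$bacterial)) / 5e4 - 1), 0.05)
})

test_that("null effects give uniform two-group p-values over taxa", {
  cs <- generate_cohort_set(
    cohort_spec("null", 30, 30, n_viral_taxa = 2000, n_bacterial_taxa = 10,
                depth_mean = 2e5),
    effect_spec(), seed = 4)
  v <- cs$studies$null$viral
  md <- cs$metadata
  case <- md$group[match(colnames(v), md$sample_id)] == "CRC"
  lv <- log1p(v)
  p <- vapply(seq_len(nrow(lv)), function(t)
    stats::t.test(lv[t, case], lv[t, !case])$p.value, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("per-study diversity SMD tracks the latent-model oracle", {
  # Oracle: the same latent tilt model (including NB count sampling)
  # simulated directly at large n.
  kappa <- 0.15; base_sd <- 1.5; eps_sd <- 0.5
  set.seed(91)
  base <- rev(qnorm(ppoints(120))) * base_sd   # the generator's fixed quantile profile
  h_latent <- function(theta, n) {
    vapply(seq_len(n), function(i) {
      l <- exp(-kappa * theta) * base + rnorm(120, sd = eps_sd)
      p <- exp(l - max(l)); p <- p / sum(p)
      shannon(rnbinom(120, mu = 1e5 * p, size = 5))
    }, numeric(1))
  }
  theta <- 0.6
  ctrl <- h_latent(0, 4000); case <- h_latent(theta, 4000)
  g_oracle <- hedges_g(ctrl, case)$estimate

  cs <- generate_cohort_set(
    cohort_spec("s", 150, 150, n_viral_taxa = 120, n_bacterial_taxa = 10,
                depth_mean = 1e5),
    effect_spec(diversity_smd_mu = theta), seed = 91)
  v <- cs$studies$s$viral
  is_case <- cs$metadata$group[match(colnames(v), cs$metadata$sample_id)] == "CRC"
  h <- apply(v, 2, shannon)
  g_emp <- hedges_g(h[!is_case], h[is_case])$estimate
  # the cohort estimate carries sampling error ~0.12 at n=150/arm
  expect_lt(abs(g_emp - g_oracle), 0.35)
  expect_gt(g_emp, 0)
})

test_that("planted copula correlation matches a direct Monte-Carlo oracle", {
  rho <- 0.8
  cs <- generate_cohort_set(
    cohort_spec("s", 200, 200, n_viral_taxa = 60, n_bacterial_taxa = 60,
                depth_mean = 5e4),
    effect_spec(xk_correlations = data.frame(
      viral_family = "vfam02", bacterial_species = "bsp040",
      rho_control = rho, rho_case = rho)), seed = 17)
  fam <- viral_family_map(rownames(cs$studies$s$viral))
  vf <- colSums(cs$studies$s$viral[fam == "vfam02", ])
  bs <- cs$studies$s$bacterial["bsp040", ]
  r_emp <- cor(vf, bs, method = "spearman")

  # Direct Monte-Carlo of the same latent model at n = 1e5: shared bivariate
  # Gaussian factor (Pearson 2 sin(pi rho / 6), loading xk_sd = 1) on the
  # log-means of the family members and the species, NB counts on top.
  set.seed(99)
  n <- 1e5
  q60 <- rev(qnorm(ppoints(60))) * 1.5   # fixed quantile base profile
  base_v <- q60[11:20]; base_b <- q60[40]   # vfam02 members; bsp040
  r_lat <- 2 * sin(pi * rho / 6)
  z1 <- rnorm(n); z2 <- r_lat * z1 + sqrt(1 - r_lat^2) * rnorm(n)
  mu_v <- exp(outer(base_v, rep(1, n)) +
                matrix(rnorm(10 * n, sd = 0.5), 10) +
                rep(z1, each = 10))
  mu_b <- exp(base_b + rnorm(n, sd = 0.5) + z2)
  # scale to plausible per-taxon depths (order matches generator output)
  mu_v <- mu_v * (200 / mean(mu_v)); mu_b <- mu_b * (200 / mean(mu_b))
  kv <- colSums(matrix(rnbinom(10 * n, mu = mu_v, size = 5), 10))
  kb <- rnbinom(n, mu = mu_b, size = 5)
  r_oracle <- cor(kv, kb, method = "spearman")
  expect_lt(abs(r_emp - r_oracle), 0.1)
})

test_that("summary-effect generator obeys its stated model", {
  expect_error(generate_summary_effects(0, -0.1, 5, 10, 1), "tau2")
  se <- generate_summary_effects(0.3, 0, k = 50, n_per_arm = 100, seed = 1)
  expect_length(se, 50)
  expect_true(all(vapply(se, function(s) abs(s$theta - 0.3) < 1e-12,
                         logical(1))))
  # null: pooled SMD near zero
  se0 <- generate_summary_effects(0, 0, k = 30, n_per_arm = 50, seed = 2)
  re <- dl_pool(lapply(se0, function(s) hedges_g(s$control, s$case)))
  expect_lt(abs(re$mu), 3 * re$se)
})

test_that("ORF hit fixtures have controlled best-hit structure", {
  hits <- generate_orf_hits(list(plan_genome("G1", c("F1", "F1", "F2"))),
                            seed = 1, n_decoys = 2)
  expect_equal(nrow(hits), 9)
  expect_false(anyDuplicated(paste(hits$genome_id, hits$orf_id,
                                   hits$protein_id)) > 0)
  ann <- annotate_genomes(hits)
  expect_equal(ann$family, "F1")
  expect_equal(ann$family_support, 2 / 3)
})
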