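#' Read a pipeline configuration from YAML
#'
#' The configuration either names per-study count/metadata TSV files
#' (`input:` block) or describes a synthetic cohort set (`synth:` block with
#' `studies:` and `effects:`), plus stage toggles (`stages:`) and numeric
#' thresholds (`params:`). See [run_pipeline()] for the recognised fields.
#'
#' @param path Path to a YAML file.
#' @return A config list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

.default_params <- function() {
  list(q_max = 0.05, n_perm = 999, n_folds = 10, n_repeats = 20,
       cross_repeats = 5, trees = 1000, prevalence_min = 0.10,
       var_frac = 0.5)
}

.config_cohorts <- function(config, seed) {
  if (!is.null(config$synth)) {
    specs <- lapply(config$synth$studies, function(s) do.call(cohort_spec, s))
    eff <- config$synth$effects
    if (!is.null(eff$da_taxa)) eff$da_taxa <- as.data.frame(eff$da_taxa)
    if (!is.null(eff$xk_correlations))
      eff$xk_correlations <- as.data.frame(eff$xk_correlations)
    effects <- do.call(effect_spec, eff %||% list())
    return(generate_cohort_set(specs, effects, seed))
  }
  if (is.null(config$input)) stop("config needs a 'synth' or 'input' block")
  inp <- config$input
  studies <- lapply(inp$studies, function(s)
    list(viral = read_counts_tsv(s$viral),
         bacterial = if (!is.null(s$bacterial)) read_counts_tsv(s$bacterial)))
  names(studies) <- vapply(inp$studies, `[[`, character(1), "study_id")
  meta <- utils::read.delim(inp$metadata, stringsAsFactors = FALSE)
  fam <- NULL
  if (!is.null(inp$family_map)) {
    fm <- utils::read.delim(inp$family_map, stringsAsFactors = FALSE)
    fam <- stats::setNames(fm[[2]], fm[[1]])
  }
  structure(list(studies = studies, metadata = meta, family_map = fam,
                 truth = NULL), class = "cohort_set")
}

.write_tsv <- function(df, out_dir, name) {
  if (!is.null(out_dir))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
}

#' Run the case-control virome meta-analysis pipeline end-to-end
#'
#' Orchestrates the stages on a multi-study cohort set: per-sample taxon
#' filtering and TMM normalization, alpha-diversity statistics with
#' per-study Wilcoxon tests (BH-adjusted across studies) and naive/adjusted
#' linear models, Hedges-g standardized mean differences pooled by
#' DerSimonian-Laird random effects (with Q and I2), Bray-Curtis PCoA and
#' PERMANOVA by study and by disease status, per-study negative-binomial
#' differential abundance with cross-study intersection counts, pooled
#' interkingdom correlation grids per disease group, and (optionally) the
#' within/cross/LODO prediction harness. When the cohorts are synthetic, a
#' truth-vs-estimate recovery table is included.
#'
#' @param config Config list (or path handled by [read_pipeline_config()]):
#'   `seed`; `synth` (with `studies` = list of [cohort_spec()] argument
#'   lists and `effects` = [effect_spec()] argument list) or `input` (paths
#'   to TSVs); `stages` (logical toggles `diversity`, `ordination`,
#'   `diffabund`, `interkingdom`, `predict`); `params` (`q_max`, `n_perm`,
#'   `n_folds`, `n_repeats`, `cross_repeats`, `trees`, `prevalence_min`,
#'   `var_frac`).
#' @param out_dir Optional directory for per-stage TSV outputs and the JSON
#'   summary; created if missing.
#' @return A report list (also written as `summary.json` when `out_dir` is
#'   given), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed %||% 1L
  stages <- utils::modifyList(
    list(diversity = TRUE, ordination = TRUE, diffabund = TRUE,
         interkingdom = TRUE, predict = FALSE),
    config$stages %||% list())
  par <- utils::modifyList(.default_params(), config$params %||% list())
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  t0 <- proc.time()[["elapsed"]]
  stage_msg <- function(name) {
    message(sprintf("[%s] %.1fs %s", format(Sys.time(), "%H:%M:%S"),
                    proc.time()[["elapsed"]] - t0, name))
  }

  stage_msg("data: acquiring cohorts")
  cohorts <- .config_cohorts(config, seed)
  meta <- cohorts$metadata
  study_ids <- names(cohorts$studies)
  report <- list(schema = "viromemeta-summary-1", seed = seed,
                 studies = study_ids)

  stage_msg("norm: filtering and TMM per study")
  norm <- lapply(cohorts$studies, function(st) {
    fv <- filter_taxa(st$viral, par$prevalence_min, par$var_frac)
    av <- tmm_normalize(fv, tmm_factors(fv))
    out <- list(viral_counts = fv, viral_abund = av)
    if (!is.null(st$bacterial)) {
      fb <- filter_taxa(st$bacterial, par$prevalence_min, par$var_frac)
      out$bacterial_counts <- fb
      out$bacterial_abund <- tmm_normalize(fb, tmm_factors(fb))
    }
    out
  })
  meta_by_study <- split(meta, meta$study)[study_ids]

  if (isTRUE(stages$diversity)) {
    stage_msg("diversity: alpha diversity + meta-analysis")
    div_rows <- list(); assoc_rows <- list()
    effects <- list(shannon = list(), heip = list(), chao1 = list())
    wilcox_p <- numeric(length(study_ids)); names(wilcox_p) <- study_ids
    for (id in study_ids) {
      dt <- diversity_table(cohorts$studies[[id]]$viral)
      md <- meta_by_study[[id]][match(dt$sample_id,
                                      meta_by_study[[id]]$sample_id), ]
      dt$study <- id; dt$group <- md$group
      div_rows[[id]] <- dt
      is_case <- md$group == "CRC"
      wilcox_p[id] <- rank_sum_test(dt$shannon[!is_case], dt$shannon[is_case])
      for (m in names(effects))
        effects[[m]][[id]] <- hedges_g(dt[[m]][!is_case], dt[[m]][is_case],
                                       label = id)
      for (adj in c(FALSE, TRUE)) {
        fit <- disease_lm(dt$shannon, md, adjusted = adj)
        assoc_rows[[paste(id, adj)]] <- data.frame(
          study = id, model = fit$model, coefficient = fit$coefficient,
          p_value = fit$p_value, stringsAsFactors = FALSE)
      }
    }
    div_tab <- do.call(rbind, div_rows)
    pooled <- lapply(effects, dl_pool)
    report$diversity <- list(
      wilcoxon = data.frame(study = study_ids, p = wilcox_p,
                            q = bh_adjust(wilcox_p), row.names = NULL),
      linear_models = do.call(rbind, c(assoc_rows, make.row.names = FALSE)),
      pooled = lapply(pooled, function(re)
        re[c("mu", "se", "ci_lower", "ci_upper", "p", "tau2", "Q", "q_p", "i2")]))
    .write_tsv(div_tab, out_dir, "diversity.tsv")
    .write_tsv(do.call(rbind, lapply(names(pooled), function(m)
      cbind(metric = m, pooled[[m]]$studies,
            mu = pooled[[m]]$mu, tau2 = pooled[[m]]$tau2,
            i2 = pooled[[m]]$i2))), out_dir, "diversity_meta.tsv")
  }

  if (isTRUE(stages$ordination)) {
    stage_msg("ordination: Bray-Curtis PCoA + PERMANOVA")
    taxa_common <- Reduce(intersect, lapply(norm, function(x)
      rownames(x$viral_abund)))
    comb <- do.call(cbind, lapply(norm, function(x)
      x$viral_abund[taxa_common, , drop = FALSE]))
    md <- meta[match(colnames(comb), meta$sample_id), ]
    d <- bray_curtis(t(comb))
    pc <- pcoa(d, k = 2)
    pm_study <- permanova(d, md$study, n_perm = par$n_perm,
                          seed = child_seed(seed, 101))
    pm_disease <- permanova(d, md$group, n_perm = par$n_perm,
                            seed = child_seed(seed, 102))
    report$ordination <- list(
      permanova_study = list(r2 = pm_study$r2, f = pm_study$pseudo_f,
                             p = pm_study$p),
      permanova_disease = list(r2 = pm_disease$r2, f = pm_disease$pseudo_f,
                               p = pm_disease$p),
      proportion_explained = pc$proportion_explained)
    .write_tsv(data.frame(sample_id = rownames(pc$coordinates),
                          pc$coordinates, study = md$study, group = md$group),
               out_dir, "pcoa.tsv")
  }

  da_b <- NULL
  if (isTRUE(stages$diffabund)) {
    stage_msg("diffabund: per-study NB tests + intersection")
    da_v <- lapply(study_ids, function(id) {
      g <- meta_by_study[[id]]$group[
        match(colnames(norm[[id]]$viral_counts),
              meta_by_study[[id]]$sample_id)]
      nb_test(norm[[id]]$viral_counts, factor(g, levels = c("control", "CRC")))
    })
    names(da_v) <- study_ids
    int_v <- da_intersection(da_v, par$q_max)
    report$diffabund <- list(viral_by_n_studies = as.list(int_v$by_n_studies),
                             viral_all_studies = int_v$taxa_all_studies)
    .write_tsv(do.call(rbind, lapply(study_ids, function(id)
      cbind(study = id, da_v[[id]]))), out_dir, "diffabund_viral.tsv")
    if (!is.null(norm[[1]]$bacterial_counts)) {
      da_b <- lapply(study_ids, function(id) {
        g <- meta_by_study[[id]]$group[
          match(colnames(norm[[id]]$bacterial_counts),
                meta_by_study[[id]]$sample_id)]
        nb_test(norm[[id]]$bacterial_counts,
                factor(g, levels = c("control", "CRC")))
      })
      names(da_b) <- study_ids
      int_b <- da_intersection(da_b, par$q_max)
      report$diffabund$bacterial_by_n_studies <- as.list(int_b$by_n_studies)
      report$diffabund$bacterial_all_studies <- int_b$taxa_all_studies
    }
  }

  if (isTRUE(stages$interkingdom) && !is.null(norm[[1]]$bacterial_abund)) {
    stage_msg("interkingdom: pooled correlation grids")
    fam_map <- cohorts$family_map
    species_sel <- .select_bacterial_species(da_b, norm, par$q_max)
    # align rows/columns across studies so the per-study grids are pooled
    # over identical (family, species) cells
    fam_rows <- function(x) {
      if (is.null(fam_map)) return(x)
      rowsum(x, fam_map[rownames(x)])
    }
    common_fams <- Reduce(intersect, lapply(norm, function(x)
      rownames(fam_rows(x$viral_abund))))
    common_species <- Reduce(intersect, c(list(species_sel), lapply(norm,
      function(x) rownames(x$bacterial_abund))))
    grids <- list(control = list(), CRC = list())
    for (id in study_ids) {
      va <- fam_rows(norm[[id]]$viral_abund)[common_fams, , drop = FALSE]
      ba <- norm[[id]]$bacterial_abund[common_species, , drop = FALSE]
      md <- meta_by_study[[id]]
      for (grp in c("control", "CRC")) {
        sm <- md$sample_id[md$group == grp]
        grids[[grp]][[id]] <- study_grid(
          va[, intersect(colnames(va), sm), drop = FALSE],
          ba[, intersect(colnames(ba), sm), drop = FALSE])
      }
    }
    pooled_xk <- lapply(grids, pooled_grid, q_max = par$q_max)
    report$interkingdom <- list(
      bacterial_species = species_sel,
      n_significant = lapply(pooled_xk, function(g)
        sum(!is.na(g$r_masked))))
    for (grp in names(pooled_xk))
      .write_tsv(cbind(group = grp, pooled_xk[[grp]]$table), out_dir,
                 paste0("interkingdom_", grp, ".tsv"))
    report$interkingdom_grids <- pooled_xk
  }

  if (isTRUE(stages$predict)) {
    stage_msg("predict: within / cross / LODO harness")
    clf <- classifier_spec(n_estimators = par$trees, seed = seed)
    dsets <- lapply(study_ids, function(id) {
      x <- t(norm[[id]]$viral_abund)
      md <- meta_by_study[[id]][match(rownames(x),
                                      meta_by_study[[id]]$sample_id), ]
      list(features = x, labels = md$group)
    })
    names(dsets) <- study_ids
    within_rep <- lapply(study_ids, function(id)
      within_study_cv(dsets[[id]]$features, dsets[[id]]$labels, clf,
                      n_folds = par$n_folds, n_repeats = par$n_repeats,
                      seed = child_seed(seed, 201 + match(id, study_ids)),
                      study_id = id))
    names(within_rep) <- study_ids
    cross_mat <- matrix(NA_real_, length(study_ids), length(study_ids),
                        dimnames = list(study_ids, study_ids))
    for (i in study_ids) for (j in study_ids) {
      if (i == j) {
        cross_mat[i, j] <- within_rep[[i]]$mean_auroc
      } else {
        cross_mat[i, j] <- cross_study(
          dsets[[i]], dsets[[j]], clf, n_repeats = par$cross_repeats,
          seed = child_seed(seed, 301 + match(i, study_ids) * 31 +
                              match(j, study_ids)),
          train_id = i, test_id = j)$mean_auroc
      }
    }
    lodo_rep <- vapply(study_ids, function(id)
      lodo(dsets, id, clf, seed = child_seed(seed, 401 + match(id, study_ids)),
           n_repeats = par$cross_repeats)$mean_auroc, numeric(1))
    report$predict <- list(
      within = vapply(within_rep, `[[`, numeric(1), "mean_auroc"),
      cross_matrix = cross_mat, lodo = lodo_rep)
    .write_tsv(data.frame(study = rownames(cross_mat), cross_mat,
                          lodo = lodo_rep), out_dir, "prediction.tsv")
  }

  if (!is.null(cohorts$truth) && isTRUE(stages$diversity)) {
    rec <- data.frame(
      study = study_ids,
      theta_planted = as.numeric(cohorts$truth$theta[study_ids]),
      smd_estimated = vapply(effects$shannon, `[[`, numeric(1), "estimate"),
      row.names = NULL, stringsAsFactors = FALSE)
    report$truth_recovery <- rec
    .write_tsv(rec, out_dir, "truth_recovery.tsv")
  }

  if (!is.null(out_dir)) {
    clean <- report
    clean$interkingdom_grids <- NULL
    if (!is.null(clean$predict))
      clean$predict$cross_matrix <- as.data.frame(clean$predict$cross_matrix)
    jsonlite::write_json(clean, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  stage_msg("done")
  invisible(report)
}

# Pick the bacterial species entering the interkingdom grid: taxa
# differentially abundant in as many studies as possible (relaxing the
# requirement until a non-empty set is found), falling back to the taxa
# with smallest per-study minimum q.
.select_bacterial_species <- function(da_b, norm, q_max, max_fallback = 20) {
  all_taxa <- rownames(norm[[1]]$bacterial_abund)
  if (is.null(da_b)) return(all_taxa)
  sig <- lapply(da_b, function(r) r$taxon[!is.na(r$q) & r$q < q_max])
  tab <- table(unlist(sig))
  for (m in rev(seq_len(length(da_b)))) {
    hit <- names(tab)[tab >= m]
    if (length(hit)) return(sort(hit))
  }
  minq <- sapply(da_b, function(r) r$q[match(all_taxa, r$taxon)])
  ord <- order(apply(as.matrix(minq), 1, min, na.rm = TRUE))
  sort(all_taxa[ord][seq_len(min(max_fallback, length(all_taxa)))])
}
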