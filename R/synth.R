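#' Describe one synthetic study cohort
#'
#' A `cohort_spec` fixes the sampling frame of one study: arm sizes, the
#' number of viral and bacterial taxa profiled, the expected per-sample
#' library size (unique read mappings), the scale of study-specific batch
#' offsets on taxon log-means, and the negative-binomial dispersion
#' (variance = m + dispersion * m^2).
#'
#' @param study_id Study label (e.g. cohort name).
#' @param n_control,n_case Number of control / case samples (each >= 2).
#' @param n_viral_taxa,n_bacterial_taxa Number of taxa per kingdom.
#' @param depth_mean Expected library size (total counts per sample).
#' @param batch_shift_sd Standard deviation of per-study, per-taxon log-mean
#'   offsets; emulates protocol/batch differences between cohorts.
#' @param dispersion Negative-binomial dispersion alpha (0 gives Poisson).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(study_id, n_control, n_case,
                        n_viral_taxa = 150, n_bacterial_taxa = 150,
                        depth_mean = 1e5, batch_shift_sd = 0.5,
                        dispersion = 0.2) {
  if (!is.character(study_id) || length(study_id) != 1L || !nzchar(study_id))
    stop("study_id must be a non-empty string")
  n_control <- as.integer(n_control); n_case <- as.integer(n_case)
  if (n_control < 2L || n_case < 2L)
    stop("n_control and n_case must each be >= 2")
  if (n_viral_taxa < 1L || n_bacterial_taxa < 1L)
    stop("zero-taxon cohort specification")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(study_id = study_id, n_control = n_control, n_case = n_case,
                 n_viral_taxa = as.integer(n_viral_taxa),
                 n_bacterial_taxa = as.integer(n_bacterial_taxa),
                 depth_mean = depth_mean, batch_shift_sd = batch_shift_sd,
                 dispersion = dispersion),
            class = "cohort_spec")
}

#' Describe the planted effects of a synthetic cohort set
#'
#' Encodes the disease signal the generator plants: a true mean standardized
#' mean difference (SMD) of case vs control viral alpha diversity with
#' between-study variance `diversity_smd_tau2` (study-level true effects are
#' drawn from Normal(mu, tau2)), a set of differentially abundant taxa with
#' log2 fold changes, and cross-kingdom Spearman correlations induced by a
#' Gaussian copula on latent taxon log-means, with separate targets per
#' disease group.
#'
#' @param diversity_smd_mu True mean SMD of viral alpha diversity (positive
#'   means higher diversity in cases).
#' @param diversity_smd_tau2 Between-study variance of the true SMD (>= 0).
#' @param da_taxa `NULL` or a data frame with columns `taxon_id`, `log2fc`
#'   giving case-vs-control log2 fold changes. Viral taxa are named
#'   `vsp###`, bacterial taxa `bsp###`.
#' @param xk_correlations `NULL` or a data frame with columns
#'   `viral_family`, `bacterial_species`, `rho_control`, `rho_case` giving
#'   target Spearman correlations between a viral family's total abundance
#'   and a bacterial species' abundance, per disease group (|rho| < 1).
#' @param metadata_model List with age/BMI distributions and the male
#'   proportion; `confounded = TRUE` shifts case age upward to exercise the
#'   covariate-adjusted model.
#' @param da_study_specific If `TRUE`, each study receives its own randomly
#'   drawn set of differentially abundant taxa of the same size and effect
#'   magnitudes (a batch-only signal: informative within a study, useless
#'   across studies).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(diversity_smd_mu = 0, diversity_smd_tau2 = 0,
                        da_taxa = NULL, xk_correlations = NULL,
                        metadata_model = list(age_mean = 60, age_sd = 10,
                                              bmi_mean = 25, bmi_sd = 4,
                                              p_male = 0.5, confounded = FALSE,
                                              confound_age_shift = 5),
                        da_study_specific = FALSE) {
  if (diversity_smd_tau2 < 0) stop("diversity_smd_tau2 must be >= 0")
  if (!is.null(da_taxa)) {
    stopifnot(is.data.frame(da_taxa),
              all(c("taxon_id", "log2fc") %in% names(da_taxa)))
  }
  if (!is.null(xk_correlations)) {
    stopifnot(is.data.frame(xk_correlations),
              all(c("viral_family", "bacterial_species",
                    "rho_control", "rho_case") %in% names(xk_correlations)))
    if (any(abs(c(xk_correlations$rho_control,
                  xk_correlations$rho_case)) >= 1))
      stop("planted correlations must satisfy |rho| < 1")
  }
  structure(list(diversity_smd_mu = diversity_smd_mu,
                 diversity_smd_tau2 = diversity_smd_tau2,
                 da_taxa = da_taxa, xk_correlations = xk_correlations,
                 metadata_model = metadata_model,
                 da_study_specific = isTRUE(da_study_specific)),
            class = "effect_spec")
}

# Internal knobs of the latent model, fixed once:
#   base_sd     - spread of taxon base log-abundances (log-normal base means)
#   eps_sd      - per-sample, per-taxon latent log-mean noise
#   xk_sd       - loading of the shared copula factor for planted pairs
#   tilt_kappa  - strength of the per-sample evenness tilt that carries the
#                 planted diversity SMD (spread multiplier exp(-kappa * u))
#   depth_logsd - log-sd of per-sample library-size variation (mean-corrected)
.synth_pars <- list(base_sd = 1.5, eps_sd = 0.5, xk_sd = 1.0,
                    tilt_kappa = 0.15, depth_logsd = 0.12)

# Spearman target -> Pearson correlation of the Gaussian copula factors.
.rho_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

viral_taxa_ids <- function(n) sprintf("vsp%03d", seq_len(n))
bacterial_taxa_ids <- function(n) sprintf("bsp%03d", seq_len(n))

#' Map viral taxa to families
#'
#' Taxa are grouped into contiguous families of (up to) `family_size`
#' members, named `vfam##`. The same rule is used by the generator and by
#' the pipeline when aggregating viral abundance to family level.
#'
#' @param taxa Character vector of viral taxon ids.
#' @param family_size Members per family.
#' @return Named character vector taxon -> family.
#' @export
viral_family_map <- function(taxa, family_size = 10) {
  fam <- sprintf("vfam%02d", ceiling(seq_along(taxa) / family_size))
  names(fam) <- taxa
  fam
}

.nb_draw <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Generate one kingdom's count matrix for one study.
# latent log-mean: tilt_j * base_t + batch_t + log(2)*lfc_t*case_j + eps_tj
# (+ copula factor rows); softmax over taxa -> proportions; NB counts at
# depth_j * p_tj so expected column sums equal the drawn depths.
.gen_kingdom <- function(base, batch, lfc, is_case, tilt, depths, eps_sd,
                         dispersion, copula_rows = NULL, copula_z = NULL,
                         xk_sd = 1.0) {
  n_t <- length(base); n_s <- length(is_case)
  L <- outer(base, tilt) + batch + log(2) * outer(lfc, as.numeric(is_case))
  L <- L + matrix(stats::rnorm(n_t * n_s, sd = eps_sd), n_t, n_s)
  if (!is.null(copula_rows)) {
    for (i in seq_along(copula_rows)) {
      rows <- copula_rows[[i]]
      L[rows, ] <- sweep(L[rows, , drop = FALSE], 2, xk_sd * copula_z[[i]], "+")
    }
  }
  P <- exp(sweep(L, 2, apply(L, 2, max), "-"))
  P <- sweep(P, 2, colSums(P), "/")
  M <- sweep(P, 2, depths, "*")
  K <- matrix(.nb_draw(as.vector(M), dispersion), n_t, n_s)
  storage.mode(K) <- "double"
  K
}

#' Generate a multi-study synthetic cohort set with known planted structure
#'
#' Draws, for each study, paired viral and bacterial taxa-by-samples count
#' matrices plus a sample metadata table, from a latent log-normal /
#' negative-binomial model: per-taxon base log-abundances shared across
#' studies, per-study per-taxon batch offsets, case-group log-fold shifts on
#' the planted differentially abundant taxa, a per-sample evenness tilt that
#' realizes the planted alpha-diversity SMD (study-level true effects
#' theta_i ~ Normal(mu, tau2)), and a Gaussian copula factor shared between
#' each planted viral family and bacterial species inducing the target
#' cross-kingdom Spearman correlations.
#'
#' @param specs List of [cohort_spec()] objects (all with the same taxa
#'   counts).
#' @param effects An [effect_spec()].
#' @param seed Integer seed; identical `(specs, effects, seed)` reproduce
#'   identical output.
#' @return A list of class `cohort_set` with elements `studies` (named list
#'   of `list(viral =, bacterial =)` count matrices), `metadata` (data frame
#'   with `sample_id`, `study`, `group`, `age`, `gender`, `bmi`),
#'   `family_map` (viral taxon -> family), and `truth` (planted parameters:
#'   per-study `theta`, the DA table per study, the correlation table, and
#'   the seed).
#' @export
generate_cohort_set <- function(specs, effects, seed) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  if (length(specs) < 1L) stop("at least one cohort_spec is required")
  if (!all(vapply(specs, inherits, logical(1), "cohort_spec")))
    stop("specs must be cohort_spec objects")
  if (!inherits(effects, "effect_spec")) stop("effects must be an effect_spec")
  nv <- unique(vapply(specs, `[[`, integer(1), "n_viral_taxa"))
  nb <- unique(vapply(specs, `[[`, integer(1), "n_bacterial_taxa"))
  if (length(nv) != 1L || length(nb) != 1L)
    stop("all studies must profile the same taxa")
  ids <- vapply(specs, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop("duplicate study_id")
  p <- .synth_pars
  vt <- viral_taxa_ids(nv); bt <- bacterial_taxa_ids(nb)
  fam_map <- viral_family_map(vt)

  with_seed(seed, {
    # taxon base log-abundances are fixed Normal quantiles in decreasing
    # order, so the taxon index is its abundance rank (vsp001 the most
    # abundant); planted effects then sit at a known abundance level
    base_v <- rev(stats::qnorm(stats::ppoints(nv))) * p$base_sd
    names(base_v) <- vt
    base_b <- rev(stats::qnorm(stats::ppoints(nb))) * p$base_sd
    names(base_b) <- bt
    theta <- stats::rnorm(length(specs), effects$diversity_smd_mu,
                          sqrt(effects$diversity_smd_tau2))
    names(theta) <- ids

    # shared or per-study DA effect vectors
    lfc_template_v <- stats::setNames(numeric(nv), vt)
    lfc_template_b <- stats::setNames(numeric(nb), bt)
    da_for_study <- vector("list", length(specs)); names(da_for_study) <- ids
    fill_lfc <- function(da) {
      lv <- lfc_template_v; lb <- lfc_template_b
      if (!is.null(da)) {
        iv <- da$taxon_id %in% vt; ib <- da$taxon_id %in% bt
        if (!all(iv | ib)) stop("unknown taxon_id in da_taxa")
        lv[da$taxon_id[iv]] <- da$log2fc[iv]
        lb[da$taxon_id[ib]] <- da$log2fc[ib]
      }
      list(v = lv, b = lb)
    }
    if (!effects$da_study_specific || is.null(effects$da_taxa)) {
      shared <- fill_lfc(effects$da_taxa)
      for (id in ids) da_for_study[[id]] <- effects$da_taxa
    }

    xk <- effects$xk_correlations
    cop_members <- NULL
    if (!is.null(xk)) {
      fam_members <- split(names(fam_map), fam_map)
      if (!all(xk$viral_family %in% names(fam_members)))
        stop("unknown viral_family in xk_correlations")
      if (!all(xk$bacterial_species %in% bt))
        stop("unknown bacterial_species in xk_correlations")
      cop_members <- lapply(seq_len(nrow(xk)), function(i)
        list(v = match(fam_members[[xk$viral_family[i]]], vt),
             b = match(xk$bacterial_species[i], bt)))
    }

    mm <- effects$metadata_model
    studies <- vector("list", length(specs)); names(studies) <- ids
    meta <- vector("list", length(specs))

    for (s in seq_along(specs)) {
      sp <- specs[[s]]
      with_seed(child_seed(seed, s), {
        n_s <- sp$n_control + sp$n_case
        is_case <- rep(c(FALSE, TRUE), c(sp$n_control, sp$n_case))
        sample_ids <- sprintf("%s_S%03d", sp$study_id, seq_len(n_s))

        if (effects$da_study_specific && !is.null(effects$da_taxa)) {
          da <- effects$da_taxa
          iv <- da$taxon_id %in% vt
          da$taxon_id[iv] <- sample(vt, sum(iv))
          da$taxon_id[!iv] <- sample(bt, sum(!iv))
          da_for_study[[sp$study_id]] <- da
          lfc <- fill_lfc(da)
        } else {
          lfc <- shared
        }

        batch_v <- stats::rnorm(nv, sd = sp$batch_shift_sd)
        batch_b <- stats::rnorm(nb, sd = sp$batch_shift_sd)
        # evenness tilt: the case group's taxon base spread is shrunk by
        # exp(-kappa * theta_s), raising its Shannon diversity; kappa is
        # calibrated so one theta unit is about one SD of Shannon at the
        # default study conditions
        tilt <- exp(-p$tilt_kappa * theta[s] * is_case)
        depths_v <- sp$depth_mean *
          exp(stats::rnorm(n_s, -p$depth_logsd^2 / 2, p$depth_logsd))
        depths_b <- sp$depth_mean *
          exp(stats::rnorm(n_s, -p$depth_logsd^2 / 2, p$depth_logsd))

        cop_z_v <- cop_z_b <- cop_rows_v <- cop_rows_b <- NULL
        if (!is.null(xk)) {
          cop_rows_v <- lapply(cop_members, `[[`, "v")
          cop_rows_b <- lapply(cop_members, `[[`, "b")
          cop_z_v <- cop_z_b <- vector("list", nrow(xk))
          for (i in seq_len(nrow(xk))) {
            r <- .rho_to_pearson(ifelse(is_case, xk$rho_case[i],
                                        xk$rho_control[i]))
            z1 <- stats::rnorm(n_s)
            z2 <- r * z1 + sqrt(pmax(0, 1 - r^2)) * stats::rnorm(n_s)
            cop_z_v[[i]] <- z1; cop_z_b[[i]] <- z2
          }
        }

        viral <- .gen_kingdom(base_v, batch_v, lfc$v, is_case, tilt, depths_v,
                              p$eps_sd, sp$dispersion, cop_rows_v, cop_z_v,
                              p$xk_sd)
        bacterial <- .gen_kingdom(base_b, batch_b, lfc$b, is_case, tilt,
                                  depths_b, p$eps_sd, sp$dispersion,
                                  cop_rows_b, cop_z_b, p$xk_sd)
        dimnames(viral) <- list(vt, sample_ids)
        dimnames(bacterial) <- list(bt, sample_ids)

        age <- stats::rnorm(n_s, mm$age_mean, mm$age_sd)
        if (isTRUE(mm$confounded))
          age <- age + mm$confound_age_shift * is_case
        meta[[s]] <- data.frame(
          sample_id = sample_ids, study = sp$study_id,
          group = ifelse(is_case, "CRC", "control"),
          age = age,
          gender = ifelse(stats::runif(n_s) < mm$p_male, "male", "female"),
          bmi = stats::rnorm(n_s, mm$bmi_mean, mm$bmi_sd),
          stringsAsFactors = FALSE)
        studies[[sp$study_id]] <- list(viral = viral, bacterial = bacterial)
      })
    }

    structure(list(
      studies = studies,
      metadata = do.call(rbind, meta),
      family_map = fam_map,
      truth = list(theta = theta, da_taxa = da_for_study,
                   xk_correlations = xk, seed = seed)),
      class = "cohort_set")
  })
}

#' Generate per-study two-arm summary data for meta-analysis recovery
#'
#' Study `i` draws a true effect `theta_i ~ Normal(mu, tau2)`; its case arm
#' values are `Normal(theta_i, 1)` and its control arm `Normal(0, 1)`, so the
#' standardized mean difference of study `i` is `theta_i`.
#'
#' @param mu True mean effect.
#' @param tau2 Between-study variance (>= 0).
#' @param k Number of studies (>= 2).
#' @param n_per_arm Samples per arm (>= 3).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(control =, case =, theta =)`.
#' @export
generate_summary_effects <- function(mu, tau2, k, n_per_arm, seed) {
  if (tau2 < 0) stop("tau2 must be >= 0")
  if (k < 2L) stop("k must be >= 2")
  if (n_per_arm < 3L) stop("n_per_arm must be >= 3")
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      theta <- stats::rnorm(1, mu, sqrt(tau2))
      list(control = stats::rnorm(n_per_arm, 0, 1),
           case = stats::rnorm(n_per_arm, theta, 1),
           theta = theta)
    })
  })
}

#' Generate an ORF-to-protein hit table with controlled best-hit structure
#'
#' Fixture generator for the taxonomy-voting stage. Each plan entry gives a
#' genome and, per ORF, the lineage of its intended best hit with a bit score
#' and e-value; the generator emits that hit plus, optionally, weaker decoy
#' hits (lower bit score, lineage drawn from the plan) so that best-hit
#' selection is exercised.
#'
#' @param genome_plan List of entries `list(genome_id =, lineages = list of
#'   named character vectors (ranks `family`, `genus`, `species`; entries may
#'   be absent), bit_scores = numeric, e_values = numeric)`, one element per
#'   ORF in `lineages`/`bit_scores`/`e_values`.
#' @param seed Integer seed (drives decoy placement).
#' @param n_decoys Decoy hits per ORF.
#' @return Data frame with columns `genome_id`, `orf_id`, `protein_id`,
#'   `bit_score`, `e_value`, `family`, `genus`, `species`.
#' @export
generate_orf_hits <- function(genome_plan, seed = 1, n_decoys = 0) {
  if (length(genome_plan) < 1L) stop("genome_plan must be non-empty")
  with_seed(seed, {
    rows <- list(); pid <- 0L
    for (g in genome_plan) {
      stopifnot(is.character(g$genome_id), length(g$lineages) >= 1L,
                length(g$bit_scores) == length(g$lineages),
                length(g$e_values) == length(g$lineages))
      for (j in seq_along(g$lineages)) {
        lin <- g$lineages[[j]]
        orf <- sprintf("%s_ORF%02d", g$genome_id, j)
        pid <- pid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = g$genome_id, orf_id = orf,
          protein_id = sprintf("P%05d", pid),
          bit_score = g$bit_scores[j], e_value = g$e_values[j],
          family = if ("family" %in% names(lin)) lin[["family"]] else NA_character_,
          genus = if ("genus" %in% names(lin)) lin[["genus"]] else NA_character_,
          species = if ("species" %in% names(lin)) lin[["species"]] else NA_character_,
          stringsAsFactors = FALSE)
        if (n_decoys > 0) {
          for (d in seq_len(n_decoys)) {
            src <- g$lineages[[sample(length(g$lineages), 1)]]
            pid <- pid + 1L
            rows[[length(rows) + 1L]] <- data.frame(
              genome_id = g$genome_id, orf_id = orf,
              protein_id = sprintf("P%05d", pid),
              bit_score = g$bit_scores[j] - stats::runif(1, 5, 30),
              e_value = g$e_values[j] * 10^stats::runif(1, 0, 2),
              family = if ("family" %in% names(src)) src[["family"]] else NA_character_,
              genus = if ("genus" %in% names(src)) src[["genus"]] else NA_character_,
              species = if ("species" %in% names(src)) src[["species"]] else NA_character_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    key <- paste(out$genome_id, out$orf_id, out$protein_id)
    if (anyDuplicated(key)) stop("duplicate (genome, ORF, protein) rows")
    out
  })
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
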