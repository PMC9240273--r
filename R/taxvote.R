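#' Select the best protein hit per ORF
#'
#' Hits with e-value at or above `e_value_max` are discarded; among the
#' survivors each ORF keeps the hit with the highest bit score. A bit-score
#' tie is broken deterministically in favour of the lexicographically
#' smallest `protein_id`, so hit-row order never affects the result. ORFs
#' with no surviving hit are omitted.
#'
#' @param hits Data frame with columns `genome_id`, `orf_id`, `protein_id`,
#'   `bit_score`, `e_value` and lineage columns `family`, `genus`, `species`
#'   (entries may be `NA`).
#' @param e_value_max E-value cutoff (hits must be strictly below it).
#' @return Data frame with one row per retained ORF.
#' @export
best_hit_per_orf <- function(hits, e_value_max = 1e-5) {
  stopifnot(e_value_max > 0)
  need <- c("orf_id", "protein_id", "bit_score", "e_value")
  if (!all(need %in% names(hits))) stop("missing hit-table columns")
  hits <- hits[hits$e_value < e_value_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$orf_id, -hits$bit_score, hits$protein_id)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$orf_id), , drop = FALSE]
}

.tax_ranks <- c("family", "genus", "species")

#' Assign taxonomy to one genome by rank-wise plurality vote
#'
#' Each rank is voted independently over the ORFs whose best-hit lineage
#' carries that rank: the plurality taxon wins and its support is the
#' fraction of votes it received. Genomes with fewer than two ORFs with
#' retained hits are `UNCLASSIFIED` at every rank, and a plurality tie
#' yields `UNCLASSIFIED` at that rank.
#'
#' @param best_hits Data frame of one best hit per ORF (one genome), as
#'   returned by [best_hit_per_orf()].
#' @param genome_id Genome identifier.
#' @return One-row data frame: `genome_id`, `n_orfs_used`, and per rank
#'   `<rank>` (assignment) and `<rank>_support` (fraction in (0, 1], `NA`
#'   when unclassified).
#' @export
vote_taxonomy <- function(best_hits, genome_id) {
  n <- nrow(best_hits)
  out <- data.frame(genome_id = genome_id, n_orfs_used = n,
                    stringsAsFactors = FALSE)
  for (rk in .tax_ranks) {
    assign_val <- "UNCLASSIFIED"; support <- NA_real_
    if (n >= 2L) {
      votes <- best_hits[[rk]]
      votes <- votes[!is.na(votes) & nzchar(votes)]
      if (length(votes)) {
        tab <- table(votes)
        winners <- names(tab)[tab == max(tab)]
        if (length(winners) == 1L) {
          assign_val <- winners
          support <- as.numeric(max(tab)) / length(votes)
        }
      }
    }
    out[[rk]] <- assign_val
    out[[paste0(rk, "_support")]] <- support
  }
  out
}

#' Annotate all genomes in an ORF hit table
#'
#' Applies [best_hit_per_orf()] and [vote_taxonomy()] per genome.
#'
#' @inheritParams best_hit_per_orf
#' @return Data frame with one row per genome (sorted by `genome_id`).
#' @export
annotate_genomes <- function(hits, e_value_max = 1e-5) {
  if (!"genome_id" %in% names(hits)) stop("missing genome_id column")
  genomes <- sort(unique(hits$genome_id))
  res <- lapply(genomes, function(g) {
    bh <- best_hit_per_orf(hits[hits$genome_id == g, , drop = FALSE],
                           e_value_max)
    vote_taxonomy(bh, g)
  })
  do.call(rbind, res)
}
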