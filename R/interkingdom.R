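#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties), via
#' [stats::cor()].
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("at least 4 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Per-study correlation grid between viral families and bacterial species
#'
#' Spearman correlation for every (viral row, bacterial row) pair over the
#' samples shared by the two abundance matrices. Pairs involving a constant
#' vector, or with fewer than `min_n` shared samples, are marked missing
#' (`NA`), never zero. Disease groups should be separated by the caller
#' (subset the columns first).
#'
#' @param viral_abund Viral families-by-samples abundance matrix.
#' @param bacterial_abund Bacterial species-by-samples abundance matrix.
#' @param min_n Minimum number of shared samples (default 4).
#' @return List with `r` (families x species correlation matrix) and `n`
#'   (number of shared samples used).
#' @export
study_grid <- function(viral_abund, bacterial_abund, min_n = 4) {
  shared <- intersect(colnames(viral_abund), colnames(bacterial_abund))
  nv <- nrow(viral_abund); nb <- nrow(bacterial_abund)
  r <- matrix(NA_real_, nv, nb,
              dimnames = list(rownames(viral_abund), rownames(bacterial_abund)))
  if (length(shared) >= min_n) {
    V <- viral_abund[, shared, drop = FALSE]
    B <- bacterial_abund[, shared, drop = FALSE]
    ok_v <- apply(V, 1, stats::sd) > 0
    ok_b <- apply(B, 1, stats::sd) > 0
    if (any(ok_v) && any(ok_b)) {
      rv <- t(apply(V[ok_v, , drop = FALSE], 1, rank))
      rb <- t(apply(B[ok_b, , drop = FALSE], 1, rank))
      r[ok_v, ok_b] <- stats::cor(t(rv), t(rb))
    }
  }
  list(r = r, n = length(shared))
}

#' Pool per-study correlation grids by Fisher-z random effects
#'
#' Each cell with at least `min_studies` non-missing per-study correlations
#' is pooled with [pool_correlation()]; p-values are Benjamini-Hochberg
#' adjusted across all tested cells (missing cells are excluded from the
#' denominator), and cells with `q >= q_max` are masked in `r_masked`.
#'
#' @param grids List of per-study grids from [study_grid()] (matching
#'   dimnames).
#' @param min_studies Minimum number of contributing studies per cell.
#' @param q_max Significance cutoff for the mask.
#' @return List of class `correlation_grid`: matrices `r`, `q`, `k`
#'   (studies per cell), `r_masked`, and a long-format data frame `table`
#'   (`viral`, `bacterial`, `pooled_r`, `p`, `q`, `k_studies`).
#' @export
pooled_grid <- function(grids, min_studies = 2, q_max = 0.05) {
  stopifnot(length(grids) >= 1)
  dn <- dimnames(grids[[1]]$r)
  r_arr <- vapply(grids, function(g) g$r,
                  matrix(0, length(dn[[1]]), length(dn[[2]])))
  dim(r_arr) <- c(length(dn[[1]]), length(dn[[2]]), length(grids))
  ns <- vapply(grids, `[[`, numeric(1), "n")
  nr <- length(dn[[1]]); nc <- length(dn[[2]])
  r_out <- q_out <- p_out <- matrix(NA_real_, nr, nc, dimnames = dn)
  k_out <- matrix(0L, nr, nc, dimnames = dn)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rs <- r_arr[i, j, ]
      use <- !is.na(rs) & ns >= 4 & abs(rs) < 1
      k_out[i, j] <- sum(use)
      if (sum(use) >= min_studies) {
        eff <- lapply(which(use), function(s)
          fisher_z_effect(rs[s], ns[s], label = names(grids)[s]))
        pc <- pool_correlation(eff)
        r_out[i, j] <- pc$r
        p_out[i, j] <- pc$p
      }
    }
  }
  q_out[] <- bh_adjust(as.vector(p_out))
  r_masked <- r_out
  r_masked[is.na(q_out) | q_out >= q_max] <- NA_real_
  tab <- data.frame(viral = rep(dn[[1]], nc),
                    bacterial = rep(dn[[2]], each = nr),
                    pooled_r = as.vector(r_out), p = as.vector(p_out),
                    q = as.vector(q_out), k_studies = as.vector(k_out),
                    stringsAsFactors = FALSE)
  structure(list(r = r_out, q = q_out, k = k_out, r_masked = r_masked,
                 table = tab[!is.na(tab$pooled_r), , drop = FALSE]),
            class = "correlation_grid")
}
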