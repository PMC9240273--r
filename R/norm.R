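#' Filter low-variance and low-prevalence taxa
#'
#' Removes taxa whose across-sample variance is below `var_frac` times the
#' median taxon variance, and taxa with zero counts in at least
#' `1 - prevalence_min` of samples. Both rules are evaluated against the
#' original matrix in a single pass (the variance median is not recomputed
#' after the prevalence rule).
#'
#' @param counts Taxa-by-samples numeric matrix.
#' @param prevalence_min Minimum fraction of samples in which a taxon must be
#'   present (non-zero); default 0.10.
#' @param var_frac Fraction of the median variance below which a taxon is
#'   dropped; default 0.5.
#' @return The surviving submatrix.
#' @export
filter_taxa <- function(counts, prevalence_min = 0.10, var_frac = 0.5) {
  check_count_matrix(counts)
  if (ncol(counts) < 2L) stop("at least two samples are required")
  v <- apply(counts, 1, stats::var)
  keep_var <- v >= var_frac * stats::median(v)
  prev <- rowMeans(counts > 0)
  keep_prev <- prev >= prevalence_min
  keep <- keep_var & keep_prev
  if (!any(keep)) stop("all taxa removed by the variance/prevalence filter")
  counts[keep, , drop = FALSE]
}

# M/A statistics of sample x against reference r (library sizes nx, nr),
# over taxa positive in both. w is the inverse asymptotic variance of M.
.tmm_ma <- function(x, r, nx, nr) {
  ok <- x > 0 & r > 0
  x <- x[ok]; r <- r[ok]
  list(ok = ok,
       M = log2((x / nx) / (r / nr)),
       A = 0.5 * log2((x / nx) * (r / nr)),
       w = (nx - x) / (nx * x) + (nr - r) / (nr * r))
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' The reference sample is the column whose 75th-percentile count fraction is
#' closest to the mean of those fractions. For every other sample, M
#' (log-ratio) and A (log-abundance) values are computed over taxa positive
#' in both sample and reference; taxa falling in the upper or lower `trim_m`
#' tail of M or `trim_a` tail of A (by rank) are excluded, and the factor is
#' two to the precision-weighted mean of the retained M values (weights =
#' inverse asymptotic variance). Factors are rescaled to geometric mean 1.
#'
#' @param counts Taxa-by-samples numeric matrix (>= 2 samples, positive
#'   library sizes).
#' @param trim_m Fraction trimmed from each tail of M; default 0.3.
#' @param trim_a Fraction trimmed from each tail of A; default 0.05.
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  check_count_matrix(counts)
  if (ncol(counts) < 2L) stop("at least two samples are required")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("samples with zero library size: ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  r <- counts[, ref]; nr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    ma <- .tmm_ma(counts[, j], r, lib[j], nr)
    if (!any(ma$ok))
      stop("sample ", colnames(counts)[j],
           " shares no positive taxon with the reference")
    M <- ma$M; A <- ma$A; w <- 1 / ma$w
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n - floor(n * trim_m)
    loA <- floor(n * trim_a) + 1; hiA <- n - floor(n * trim_a)
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep) || !is.finite(sum(w[keep])) || sum(w[keep]) == 0) return(1)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Apply TMM factors to obtain effective-library CPM
#'
#' Each entry becomes `count / (library_size * factor) * 1e6`, i.e.
#' counts-per-million on the effective (factor-adjusted) library size.
#'
#' @param counts Taxa-by-samples numeric matrix.
#' @param factors Per-sample factors from [tmm_factors()] (names must match
#'   the sample set).
#' @return Numeric matrix of normalized abundances.
#' @export
tmm_normalize <- function(counts, factors) {
  check_count_matrix(counts)
  if (!setequal(colnames(counts), names(factors)))
    stop("factor names must match sample names")
  factors <- factors[colnames(counts)]
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("samples with zero library size: ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  sweep(counts, 2, lib * factors, "/") * 1e6
}
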