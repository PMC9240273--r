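#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_t - y_t| / sum (x_t + y_t)` between the abundance
#' profiles of every sample pair.
#'
#' @param abundance Samples-by-taxa numeric matrix (non-negative; no all-zero
#'   sample).
#' @return Symmetric matrix with zero diagonal and sample dimnames.
#' @export
bray_curtis <- function(abundance) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("abundance must be a numeric matrix (samples x taxa)")
  if (any(abundance < 0)) stop("abundance must be non-negative")
  rs <- rowSums(abundance)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(abundance)[rs == 0], collapse = ", "))
  n <- nrow(abundance)
  d <- matrix(0, n, n, dimnames = list(rownames(abundance), rownames(abundance)))
  for (i in seq_len(n - 1)) {
    xi <- abundance[i, ]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - abundance[j, ])) / (rs[i] + rs[j])
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: the squared distance matrix is double-centered
#' (`B = -1/2 J D^2 J`), eigendecomposed, and the top `k` positive
#' eigenpairs retained; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. The proportion explained uses the sum of
#' positive eigenvalues as denominator (negative eigenvalues, which arise
#' for non-Euclidean dissimilarities such as Bray-Curtis, are dropped).
#' Axis signs are fixed so that each axis's largest-magnitude coordinate is
#' positive.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Number of axes to keep (`k <= n - 1`).
#' @return List with `coordinates` (n x k), `eigenvalues` (all positive
#'   eigenvalues), and `proportion_explained` (for the kept axes).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n - 1) stop("k must be <= n - 1")
  if (max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with zero diagonal")
  d2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-10 * max(abs(e$values))
  if (!any(pos)) stop("no positive eigenvalue; d carries no metric structure")
  lam <- e$values[pos]
  k_use <- min(k, length(lam))
  coords <- e$vectors[, which(pos)[seq_len(k_use)], drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k_use)]), k_use)
  for (a in seq_len(k_use)) {
    imax <- which.max(abs(coords[, a]))
    if (coords[imax, a] < 0) coords[, a] <- -coords[, a]
  }
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(k_use)))
  list(coordinates = coords, eigenvalues = lam,
       proportion_explained = lam[seq_len(k_use)] / sum(lam))
}

.permanova_f <- function(d2, labels, n, a) {
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(f = f, r2 = ss_between / ss_total, ss_total = ss_total,
       ss_within = ss_within, ss_between = ss_between)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, pseudo-F
#' `(SS_between / (a-1)) / (SS_within / (n-a))`, and the permutation p-value
#' `(1 + #[F_perm >= F_obs]) / (1 + n_perm)` under seeded free label
#' permutation.
#'
#' @param d Distance matrix (as from [bray_curtis()]).
#' @param labels Group label per sample (>= 2 groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `permanova_result`: `r2`, `pseudo_f`, `p`,
#'   `n_perm`, plus the sums of squares.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match the distance matrix")
  a <- length(unique(labels))
  if (a < 2) stop("at least two groups are required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  d2 <- d^2
  obs <- .permanova_f(d2, labels, n, a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      .permanova_f(d2, sample(labels), n, a)$f >= obs$f - 1e-12
    }, logical(1)))
  })
  structure(list(r2 = obs$r2, pseudo_f = obs$f,
                 p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
                 ss_total = obs$ss_total, ss_within = obs$ss_within,
                 ss_between = obs$ss_between, n = n, n_groups = a),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$r2, x$pseudo_f, x$p, x$n_perm))
  invisible(x)
}
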