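#' Construct a per-study effect
#'
#' The atom of the meta-analysis: an estimate with its sampling variance.
#'
#' @param estimate Effect estimate `y_i`.
#' @param variance Sampling variance `v_i` (> 0).
#' @param n1,n2 Optional arm sizes.
#' @param label Optional study label.
#' @return Object of class `study_effect`.
#' @export
study_effect <- function(estimate, variance, n1 = NA_integer_,
                         n2 = NA_integer_, label = NA_character_) {
  if (!is.finite(estimate)) stop("estimate must be finite")
  if (!is.finite(variance) || variance <= 0) stop("variance must be > 0")
  structure(list(estimate = estimate, variance = variance,
                 n1 = n1, n2 = n2, label = label),
            class = "study_effect")
}

#' Hedges' g standardized mean difference
#'
#' `g = J * (mean(case) - mean(control)) / s_pooled` with the small-sample
#' correction `J = 1 - 3 / (4 nu - 1)`, `nu = n1 + n2 - 2`; positive values
#' mean higher in the case arm. The sampling variance is
#' `(n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))`.
#'
#' @param control,case Numeric vectors (each >= 2 values).
#' @param correct Apply the Hedges small-sample correction (default `TRUE`;
#'   `FALSE` gives Cohen's d).
#' @param label Optional study label.
#' @return A [study_effect()].
#' @export
hedges_g <- function(control, case, correct = TRUE, label = NA_character_) {
  n1 <- length(control); n2 <- length(case)
  if (n1 < 2L || n2 < 2L) stop("both arms need >= 2 values")
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(control) + (n2 - 1) * stats::var(case)) / nu
  if (sp2 <= 0) stop("zero pooled variance")
  j <- if (correct) 1 - 3 / (4 * nu - 1) else 1
  g <- j * (mean(case) - mean(control)) / sqrt(sp2)
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  study_effect(g, v, n1, n2, label)
}

.effects_to_df <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("estimate", "variance") %in% names(effects)))
    df <- effects
    if (is.null(df$label)) df$label <- paste0("study", seq_len(nrow(df)))
    return(df)
  }
  if (inherits(effects, "study_effect")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, logical(1), "study_effect")))
  data.frame(
    estimate = vapply(effects, `[[`, numeric(1), "estimate"),
    variance = vapply(effects, `[[`, numeric(1), "variance"),
    label = vapply(seq_along(effects), function(i)
      if (is.na(effects[[i]]$label)) paste0("study", i) else effects[[i]]$label,
      character(1)),
    stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments estimation of the between-study variance:
#' fixed-effect weights `w_i = 1/v_i` give Cochran's
#' `Q = sum w_i (y_i - ybar_w)^2`; then
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with `df = k - 1`.
#' Random-effects weights `1 / (v_i + tau2)` yield the pooled estimate, its
#' standard error, a normal test of `mu = 0`, the Q-test p-value
#' (chi-square with `df`), and `I2 = max(0, (Q - df) / Q) * 100`.
#'
#' @param effects List of [study_effect()]s, or a data frame with columns
#'   `estimate`, `variance` (and optionally `label`).
#' @return Object of class `re_pool` with fields `mu`, `se`, `ci_lower`,
#'   `ci_upper`, `z`, `p`, `tau2`, `Q`, `df`, `q_p`, `i2` (percent), `k`,
#'   and the per-study table `studies` (with random-effects `weight`).
#' @export
dl_pool <- function(effects) {
  df_e <- .effects_to_df(effects)
  k <- nrow(df_e)
  if (k < 2L) stop("at least two studies are required")
  y <- df_e$estimate; v <- df_e$variance
  if (any(v <= 0)) stop("all sampling variances must be > 0")
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df_q <- k - 1
  tau2 <- max(0, (Q - df_q) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- mu / se
  i2 <- if (Q > 0) max(0, (Q - df_q) / Q) * 100 else 0
  structure(list(
    mu = mu, se = se,
    ci_lower = mu - 1.96 * se, ci_upper = mu + 1.96 * se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    tau2 = tau2, Q = Q, df = df_q,
    q_p = stats::pchisq(Q, df_q, lower.tail = FALSE),
    i2 = i2, k = k,
    studies = transform(df_e, weight = ws / sum(ws))),
    class = "re_pool")
}

#' @export
print.re_pool <- function(x, ...) {
  cat(sprintf("Random-effects pooling (DerSimonian-Laird), k = %d studies\n", x$k))
  cat(sprintf("  mu = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], z = %.3f, p = %.3g\n",
              x$mu, x$se, x$ci_lower, x$ci_upper, x$z, x$p))
  cat(sprintf("  tau2 = %.4f, Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
              x$tau2, x$Q, x$df, x$q_p, x$i2))
  invisible(x)
}

#' Fisher z-transformed correlation effect
#'
#' `y = atanh(r)` with sampling variance `1 / (n - 3)`.
#'
#' @param r Correlation coefficient with `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param label Optional study label.
#' @return A [study_effect()].
#' @export
fisher_z_effect <- function(r, n, label = NA_character_) {
  if (!is.finite(r) || abs(r) >= 1) stop("|r| must be < 1")
  if (n <= 3) stop("n must be >= 4")
  study_effect(atanh(r), 1 / (n - 3), label = label)
}

#' Pool correlations across studies on the Fisher-z scale
#'
#' Applies [dl_pool()] to z-transformed correlations and back-transforms the
#' pooled estimate with `tanh`; the p-value is the z-scale normal test.
#'
#' @param effects List of [fisher_z_effect()]s (or anything [dl_pool()]
#'   accepts, on the z scale).
#' @return List with `r` (pooled correlation), `ci_lower`, `ci_upper` (back-
#'   transformed), `p`, and the full z-scale `re_pool` as `pooled`.
#' @export
pool_correlation <- function(effects) {
  re <- dl_pool(effects)
  list(r = tanh(re$mu), ci_lower = tanh(re$ci_lower),
       ci_upper = tanh(re$ci_upper), p = re$p, pooled = re)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input validation;
#' `NA` entries are preserved and excluded from the denominator.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
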