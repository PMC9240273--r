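#' Shannon diversity index (natural log)
#'
#' `H = -sum p_i log(p_i)` over the positive entries of a count or abundance
#' vector, with `p_i = x_i / sum(x)`.
#'
#' @param x Non-negative numeric vector with at least one positive entry.
#' @return Shannon index in nats.
#' @export
shannon <- function(x) {
  if (any(x < 0) || any(!is.finite(x))) stop("counts must be finite and non-negative")
  if (sum(x) <= 0) stop("all-zero abundance vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Heip evenness
#'
#' `(exp(H) - 1) / (S - 1)` where `H` is the Shannon index and `S` the
#' observed richness; equals 1 for a uniform community. For `S = 1` the
#' value is defined as 0.
#'
#' @inheritParams shannon
#' @return Evenness in `[0, 1]`.
#' @export
heip_evenness <- function(x) {
  s <- sum(x > 0)
  if (s <= 1) {
    if (s == 0) stop("all-zero abundance vector")
    return(0)
  }
  (exp(shannon(x)) - 1) / (s - 1)
}

#' Chao1 richness estimator
#'
#' `S + f1^2 / (2 f2)` when doubletons exist, and the bias-corrected form
#' `S + f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`, where `f1`/`f2` are the
#' numbers of taxa observed exactly once/twice.
#'
#' @param x Non-negative integer count vector.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(x) {
  if (any(x < 0) || any(x != round(x))) stop("chao1 requires integer counts")
  if (sum(x) <= 0) stop("all-zero count vector")
  s <- sum(x > 0)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha-diversity table
#'
#' @param counts Taxa-by-samples count matrix (raw integer counts; Chao1 is
#'   only defined on integers).
#' @return Data frame with one row per sample: `sample_id`, `shannon`,
#'   `heip`, `chao1`, `richness`.
#' @export
diversity_table <- function(counts) {
  check_count_matrix(counts)
  data.frame(
    sample_id = colnames(counts),
    shannon = apply(counts, 2, shannon),
    heip = apply(counts, 2, heip_evenness),
    chao1 = apply(counts, 2, chao1),
    richness = apply(counts, 2, function(x) sum(x > 0)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin wrapper over [stats::wilcox.test()]: exact enumeration for small
#' tie-free samples, normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)$p.value)
}

#' Disease association of alpha diversity by linear model
#'
#' Fits ordinary least squares on `Y = log(diversity + 1e-6)`, either the
#' naive model `Y ~ Disease` or the adjusted model
#' `Y ~ Disease + Age + Gender + BMI`, and returns the disease-term
#' coefficient with its two-sided t-test p-value. Disease is coded 1 for the
#' case group, so a positive coefficient means higher diversity in cases.
#'
#' @param diversity Per-sample diversity values.
#' @param metadata Data frame aligned with `diversity`; must contain `group`
#'   (values `CRC`/`control`), and `age`, `gender`, `bmi` when
#'   `adjusted = TRUE`.
#' @param adjusted Include age, gender and BMI covariates.
#' @param case_level Metadata `group` value treated as disease; default
#'   `"CRC"`.
#' @return List of class `disease_lm`: `coefficient`, `p_value`, `model`
#'   (`"naive"` or `"adjusted"`), and the underlying `lm` fit.
#' @export
disease_lm <- function(diversity, metadata, adjusted = FALSE,
                       case_level = "CRC") {
  if (length(diversity) != nrow(metadata))
    stop("diversity and metadata must have matching length")
  if (!"group" %in% names(metadata)) stop("metadata must contain 'group'")
  d <- data.frame(y = log(diversity + 1e-6),
                  disease = as.numeric(metadata$group == case_level))
  if (adjusted) {
    need <- c("age", "gender", "bmi")
    miss <- setdiff(need, names(metadata))
    if (length(miss))
      stop("missing covariates in adjusted mode: ", paste(miss, collapse = ", "))
    d$age <- metadata$age
    d$gender <- as.numeric(metadata$gender == "male")
    d$bmi <- metadata$bmi
    fit <- stats::lm(y ~ disease + age + gender + bmi, data = d)
  } else {
    fit <- stats::lm(y ~ disease, data = d)
  }
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    ali <- is.na(stats::coef(fit))
    stop("collinear design; aliased columns: ",
         paste(names(stats::coef(fit))[ali], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  structure(list(coefficient = sm["disease", "Estimate"],
                 p_value = sm["disease", "Pr(>|t|)"],
                 model = if (adjusted) "adjusted" else "naive",
                 fit = fit),
            class = "disease_lm")
}
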