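# Fast deterministic classifier for harness-behaviour tests: scores by the
# distance to the class centroids of the training features.
centroid_clf <- list(
  fit = function(x, y) list(c1 = colMeans(x[y, , drop = FALSE]),
                            c0 = colMeans(x[!y, , drop = FALSE])),
  score = function(m, x) {
    d0 <- sqrt(rowSums(sweep(x, 2, m$c0)^2))
    d1 <- sqrt(rowSums(sweep(x, 2, m$c1)^2))
    d0 - d1
  })

# Mock classifier that records which samples it trains on (leakage check).
recording_clf <- function(log_env) list(
  fit = function(x, y) { log_env$train <- c(log_env$train, list(rownames(x))); NULL },
  score = function(m, x) { log_env$test <- c(log_env$test, list(rownames(x)))
    seq_len(nrow(x)) })

sep_data <- function(n = 60, p = 20, shift = 2, seed = 1, batch = 0) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("smp%02d_%d", seq_len(n), seed),
                              sprintf("f%02d", seq_len(p))))
  x[y, 1] <- x[y, 1] + shift
  x <- x + batch
  list(features = x, labels = y)
}

test_that("AUROC equals the brute-force pairwise concordance oracle", {
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(5, 4, 3), c(1, 1, 0)), 1)
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(30)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    s <- round(runif(n), 2)           # rounded -> ties exercised
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    pairs <- expand.grid(p = which(y), n = which(!y))
    oracle <- mean((s[pairs$p] > s[pairs$n]) + 0.5 * (s[pairs$p] == s[pairs$n]))
    expect_equal(auroc(s, y), oracle, tolerance = 1e-12)
  }
})

test_that("within-study CV is null-calibrated, detects separability, and is
           deterministic", {
  d0 <- sep_data(n = 120, shift = 0, seed = 2)
  r0 <- within_study_cv(d0$features, d0$labels, centroid_clf, n_repeats = 5)
  expect_lt(abs(r0$mean_auroc - 0.5), 0.1)
  d1 <- sep_data(n = 60, shift = 3, seed = 3)
  r1 <- within_study_cv(d1$features, d1$labels, centroid_clf, n_repeats = 5)
  expect_gt(r1$mean_auroc, 0.95)
  expect_length(r1$aurocs, 50)
  # same seed -> identical report (with the stochastic forest too)
  rf <- classifier_spec(n_estimators = 30)
  a <- within_study_cv(d1$features, d1$labels, rf, n_repeats = 2, seed = 9)
  b <- within_study_cv(d1$features, d1$labels, rf, n_repeats = 2, seed = 9)
  expect_identical(a, b)
  # class smaller than n_folds -> error
  idx <- c(1:6, 31:36)    # 6 per class, fewer than n_folds
  expect_error(within_study_cv(d1$features[idx, ], d1$labels[idx],
                               centroid_clf, n_folds = 10), "n_folds")
})

test_that("within-study CV never trains on a held-out sample", {
  env <- new.env(); env$train <- list(); env$test <- list()
  d <- sep_data(n = 40, seed = 4)
  within_study_cv(d$features, d$labels, recording_clf(env),
                  n_folds = 5, n_repeats = 2, seed = 1)
  expect_length(env$train, 10)
  for (i in seq_along(env$train)) {
    expect_length(intersect(env$train[[i]], env$test[[i]]), 0)
    expect_setequal(c(env$train[[i]], env$test[[i]]), rownames(d$features))
  }
})

test_that("cross-study transfer uses the feature intersection and detects
           shared but not batch-only signal", {
  tr <- sep_data(n = 60, shift = 3, seed = 5)
  te <- sep_data(n = 60, shift = 3, seed = 6)
  r <- cross_study(tr, te, centroid_clf, n_repeats = 1)
  expect_gt(r$mean_auroc, 0.85)
  # resubstitution ordering: test = train scores at least as well
  rr <- cross_study(tr, tr, centroid_clf, n_repeats = 1)
  expect_gte(rr$mean_auroc + 1e-9, r$mean_auroc)
  # batch-only signal: shift on a different feature per study
  tr2 <- sep_data(n = 60, shift = 0, seed = 7); te2 <- sep_data(n = 60, shift = 0, seed = 8)
  tr2$features[tr2$labels, 2] <- tr2$features[tr2$labels, 2] + 3
  te2$features[te2$labels, 9] <- te2$features[te2$labels, 9] + 3
  w2 <- within_study_cv(tr2$features, tr2$labels, centroid_clf, n_repeats = 3)
  x2 <- cross_study(tr2, te2, centroid_clf, n_repeats = 1)
  expect_gt(w2$mean_auroc, 0.7)
  expect_lt(abs(x2$mean_auroc - 0.5), 0.15)
  # disjoint feature spaces -> error
  te3 <- te; colnames(te3$features) <- paste0("other_", colnames(te3$features))
  expect_error(cross_study(tr, te3, centroid_clf), "intersection")
})

test_that("LODO pools training sets and behaves at the null", {
  sets <- lapply(1:4, function(s) sep_data(n = 40, shift = 2, seed = s))
  names(sets) <- paste0("S", 1:4)
  r <- lodo(sets, "S2", centroid_clf, seed = 1)
  expect_gt(r$mean_auroc, 0.8)
  expect_setequal(r$train_ids, c("S1", "S3", "S4"))
  # held-out labels permuted -> chance performance
  sets2 <- sets
  set.seed(11); sets2$S2$labels <- sample(sets2$S2$labels)
  expect_lt(abs(lodo(sets2, "S2", centroid_clf)$mean_auroc - 0.5), 0.2)
  expect_error(lodo(sets, "nope", centroid_clf), "not found")
  # deterministic under fixed seeds with the forest
  rf <- classifier_spec(n_estimators = 30)
  expect_identical(lodo(sets, "S1", rf, seed = 3), lodo(sets, "S1", rf, seed = 3))
})
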