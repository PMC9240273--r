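#' Classifier specification
#'
#' The harness treats the classifier as a contract: fit on a features-by-
#' samples design plus binary labels, return continuous scores for new
#' samples. The default is a random forest ([ranger::ranger()]) with 1000
#' trees. A custom classifier can be supplied as
#' `list(fit = function(x, y) model, score = function(model, x) numeric)`.
#'
#' @param kind Classifier kind; only `"random-forest"` is built in.
#' @param n_estimators Number of trees (>= 1).
#' @param seed Base seed for classifier randomness.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = "random-forest", n_estimators = 1000,
                            seed = 1) {
  if (n_estimators < 1) stop("n_estimators must be >= 1")
  structure(list(kind = kind, n_estimators = as.integer(n_estimators),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

.is_custom_clf <- function(clf) {
  is.list(clf) && !inherits(clf, "classifier_spec") &&
    is.function(clf$fit) && is.function(clf$score)
}

# Fit on (x_train, y_train) and score x_test; rows are samples.
.fit_score <- function(clf, x_train, y_train, x_test, seed) {
  if (.is_custom_clf(clf)) {
    model <- clf$fit(x_train, y_train)
    return(clf$score(model, x_test))
  }
  if (!inherits(clf, "classifier_spec") || clf$kind != "random-forest")
    stop("unsupported classifier kind")
  y <- factor(y_train, levels = c(FALSE, TRUE))
  df <- as.data.frame(x_train)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  fit <- ranger::ranger(x = df, y = y, num.trees = clf$n_estimators,
                        probability = TRUE, seed = seed, num.threads = 1)
  dft <- as.data.frame(x_test)
  colnames(dft) <- colnames(df)
  stats::predict(fit, data = dft, num.threads = 1)$predictions[, "TRUE"]
}

.as_binary <- function(labels, positive = "CRC") {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  as.character(labels) == positive
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted one half (Mann-Whitney midrank construction).
#'
#' @param scores Continuous classifier scores.
#' @param labels Binary labels (logical, 0/1, or character with positive
#'   class `positive`).
#' @param positive Positive-class label for character input.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = "CRC") {
  y <- .as_binary(labels, positive)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified fold assignment: within each class, shuffle and deal round-robin.
.stratified_folds <- function(y, n_folds) {
  if (min(table(y)) < n_folds)
    stop("each class needs >= n_folds samples for stratified folds")
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

.eval_report <- function(setting, train_ids, test_id, aurocs) {
  structure(list(setting = setting, train_ids = train_ids, test_id = test_id,
                 mean_auroc = mean(aurocs), aurocs = aurocs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("[%s] train: %s | test: %s | mean AUROC = %.3f (%d runs)\n",
              x$setting, paste(x$train_ids, collapse = "+"),
              x$test_id, x$mean_auroc, length(x$aurocs)))
  invisible(x)
}

#' Within-study repeated stratified cross-validation
#'
#' Stratified `n_folds`-fold cross-validation repeated `n_repeats` times
#' with fresh fold assignments per repeat; AUROC is computed per held-out
#' fold and the report carries the mean over all `n_folds * n_repeats` fold
#' AUROCs.
#'
#' @param features Samples-by-features numeric matrix.
#' @param labels Binary labels over samples.
#' @param clf A [classifier_spec()] or custom classifier list.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats (default 20).
#' @param seed Integer seed driving fold assignment and classifier seeds.
#' @param study_id Label recorded in the report.
#' @return An `eval_report`.
#' @export
within_study_cv <- function(features, labels, clf = classifier_spec(),
                            n_folds = 10, n_repeats = 20, seed = 1,
                            study_id = "study") {
  y <- .as_binary(labels)
  if (nrow(features) != length(y)) stop("features/labels mismatch")
  aurocs <- with_seed(seed, {
    out <- numeric(0)
    for (rep_i in seq_len(n_repeats)) {
      fold <- .stratified_folds(y, n_folds)
      for (f in seq_len(n_folds)) {
        te <- fold == f
        scores <- .fit_score(clf, features[!te, , drop = FALSE], y[!te],
                             features[te, , drop = FALSE],
                             child_seed(seed, rep_i * n_folds + f))
        out <- c(out, auroc(scores, y[te]))
      }
    }
    out
  })
  .eval_report("within", study_id, study_id, aurocs)
}

#' Cross-study transfer evaluation
#'
#' Fits on the full training study and scores the test study, over the
#' intersection of feature identifiers (column names), repeating with fresh
#' classifier seeds.
#'
#' @param train,test Lists `list(features =, labels =)` with samples-by-
#'   features matrices carrying feature column names.
#' @param clf A [classifier_spec()] or custom classifier list.
#' @param n_repeats Number of refits with fresh seeds (default 20).
#' @param seed Integer seed.
#' @param train_id,test_id Labels recorded in the report.
#' @return An `eval_report`.
#' @export
cross_study <- function(train, test, clf = classifier_spec(), n_repeats = 20,
                        seed = 1, train_id = "train", test_id = "test") {
  common <- intersect(colnames(train$features), colnames(test$features))
  if (length(common) == 0) stop("empty feature intersection")
  xtr <- train$features[, common, drop = FALSE]
  xte <- test$features[, common, drop = FALSE]
  ytr <- .as_binary(train$labels); yte <- .as_binary(test$labels)
  aurocs <- vapply(seq_len(n_repeats), function(i) {
    auroc(.fit_score(clf, xtr, ytr, xte, child_seed(seed, i)), yte)
  }, numeric(1))
  .eval_report("cross", train_id, test_id, aurocs)
}

#' Leave-one-dataset-out evaluation
#'
#' Pools every dataset except `held_out` (over the intersection of feature
#' identifiers across all datasets), fits once per repeat, and evaluates
#' AUROC on the held-out dataset.
#'
#' @param datasets Named list of `list(features =, labels =)` entries.
#' @param held_out Name of the dataset to hold out.
#' @param clf A [classifier_spec()] or custom classifier list.
#' @param seed Integer seed.
#' @param n_repeats Number of refits with fresh seeds (default 1).
#' @return An `eval_report`.
#' @export
lodo <- function(datasets, held_out, clf = classifier_spec(), seed = 1,
                 n_repeats = 1) {
  if (!held_out %in% names(datasets)) stop("held_out dataset not found")
  if (length(datasets) < 2) stop("lodo needs >= 2 datasets")
  common <- Reduce(intersect, lapply(datasets, function(d) colnames(d$features)))
  if (length(common) == 0) stop("empty feature intersection")
  tr <- datasets[setdiff(names(datasets), held_out)]
  xtr <- do.call(rbind, lapply(tr, function(d) d$features[, common, drop = FALSE]))
  ytr <- unlist(lapply(tr, function(d) .as_binary(d$labels)), use.names = FALSE)
  xte <- datasets[[held_out]]$features[, common, drop = FALSE]
  yte <- .as_binary(datasets[[held_out]]$labels)
  aurocs <- vapply(seq_len(n_repeats), function(i) {
    auroc(.fit_score(clf, xtr, ytr, xte, child_seed(seed, i)), yte)
  }, numeric(1))
  .eval_report("lodo", setdiff(names(datasets), held_out), held_out, aurocs)
}
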