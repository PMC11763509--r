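#' Fit an extremely randomized trees classifier with impurity importances
#'
#' Ensemble of extremely randomized trees: every tree sees the full sample
#' (no bootstrap) and split thresholds are drawn at random, with Gini
#' impurity scoring. Feature importances are mean impurity decrease,
#' normalized to sum to 1.
#'
#' @param features Numeric matrix or data.frame of predictors.
#' @param labels Two-class vector.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @return List of class `tki_ensemble` with `model` (a [ranger::ranger]
#'   fit) and `importance` (named, sums to 1).
#' @export
fit_tree_ensemble <- function(features, labels, n_trees = 100L, seed = 1L) {
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; a classifier needs two", call. = FALSE)
  }
  df <- as.data.frame(features)
  df$.outcome <- factor(labels)
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    num.trees = n_trees, splitrule = "extratrees", num.random.splits = 1L,
    replace = FALSE, sample.fraction = 1, importance = "impurity",
    probability = TRUE, seed = seed, num.threads = 1L
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  structure(list(model = fit, importance = imp), class = "tki_ensemble")
}

#' @export
print.tki_ensemble <- function(x, ...) {
  cat(sprintf("Extremely randomized trees (%d trees)\nTop importances:\n",
              x$model$num.trees))
  print(round(sort(x$importance, decreasing = TRUE), 3))
  invisible(x)
}

classification_metrics <- function(truth, score, pred, positive) {
  pos <- truth == positive
  tp <- sum(pred == positive & pos)
  tn <- sum(pred != positive & !pos)
  fp <- sum(pred == positive & !pos)
  fn <- sum(pred != positive & pos)
  n <- length(truth)
  accuracy <- (tp + tn) / n
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  auc <- if (length(unique(truth)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(
      response = factor(pos, levels = c(FALSE, TRUE)),
      predictor = score, quiet = TRUE,
      levels = c(FALSE, TRUE), direction = "<")))
  } else NA_real_
  c(accuracy = accuracy, auc = auc, recall = recall, precision = precision,
    f1 = f1, kappa = kappa, mcc = mcc)
}

stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated classification metrics
#'
#' Stratified k-fold cross-validation of either the extremely randomized
#' trees classifier or the constant dummy baseline. Per-fold accuracy, AUC,
#' recall, precision, F1, Cohen's kappa and Matthews correlation are
#' averaged over folds; AUC is computed from predicted positive-class
#' scores. A degenerate fold containing one class is skipped with a warning.
#'
#' @param features Numeric matrix or data.frame of predictors.
#' @param labels Two-class vector; the positive class is the highest level.
#' @param model `"extratrees"` or `"dummy"`.
#' @param n_folds Folds (default 10); every class must have at least
#'   `n_folds` members.
#' @param n_trees Trees for the ensemble.
#' @param seed Integer seed (fold assignment and tree fitting).
#' @return One-row `data.frame` (`model_name`, one column per metric).
#' @export
evaluate_classifier <- function(features, labels,
                                model = c("extratrees", "dummy"),
                                n_folds = 10L, n_trees = 100L, seed = 1L) {
  model <- match.arg(model)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("labels must contain two classes", call. = FALSE)
  if (any(table(labels) < n_folds)) {
    stop("each class must have at least n_folds members", call. = FALSE)
  }
  positive <- classes[2L]
  x <- as.matrix(features)
  fold <- stratified_folds(labels, n_folds, seed)
  rows <- list()
  for (f in seq_len(n_folds)) {
    te <- fold == f
    if (length(unique(labels[te])) < 2L || length(unique(labels[!te])) < 2L) {
      warning(sprintf("fold %d is degenerate (one class); skipped", f),
              call. = FALSE)
      next
    }
    if (model == "extratrees") {
      fit <- fit_tree_ensemble(x[!te, , drop = FALSE], labels[!te],
                               n_trees = n_trees, seed = seed + f)
      pr <- stats::predict(fit$model,
                           data = as.data.frame(x[te, , drop = FALSE]))$predictions
      score <- pr[, as.character(positive)]
      pred <- ifelse(score >= 0.5, classes[2L], classes[1L])
    } else {
      # constant positive-class predictor with tied scores
      score <- rep(0.5, sum(te))
      pred <- rep(positive, sum(te))
    }
    rows[[length(rows) + 1L]] <- classification_metrics(
      labels[te], score, pred, positive)
  }
  if (!length(rows)) stop("all folds were degenerate", call. = FALSE)
  avg <- colMeans(do.call(rbind, rows))
  cbind(data.frame(model_name = if (model == "extratrees")
    "Extra Trees Classifier" else "Dummy Classifier"),
    as.data.frame(as.list(avg)))
}

#' Constant-baseline metrics
#'
#' Cross-validated metrics of the constant predictor that always outputs the
#' positive class with a tied score: recall 1, AUC 0.5, kappa and Matthews
#' correlation 0, accuracy equal to the positive prevalence.
#'
#' @inheritParams evaluate_classifier
#' @return One-row `data.frame` of metrics.
#' @export
dummy_metrics <- function(features, labels, n_folds = 10L, seed = 1L) {
  evaluate_classifier(features, labels, model = "dummy",
                      n_folds = n_folds, seed = seed)
}
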