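#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `folds` folds, shuffling within each class so
#' every fold holds both classes in roughly the dataset's proportion. The
#' assignment depends only on `labels` and `seed` and leaves the caller's RNG
#' stream untouched.
#'
#' @param labels 0/1 vector.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..folds) per sample.
#' @export
stratified_folds <- function(labels, folds, seed = 1) {
  stopifnot(folds >= 2)
  if (length(labels) < folds) stop("fewer samples than folds")
  id <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  id
}

#' Cross-validated linear-SVM accuracy of a feature subset
#'
#' The wrapper fitness: mean held-out accuracy of a linear support vector
#' machine ([svm_linear_fit()], error penalty `C`; the pipeline has already
#' z-scored the data) over stratified folds, trained on the masked columns
#' only. The fold assignment depends only on the labels and the seed, never on
#' the mask, so subsets are compared on identical splits.
#'
#' @param mask 0/1 or logical mask over the dataset's columns; must select at
#'   least one.
#' @param dataset a complete [clinical_dataset()] containing both classes.
#' @param folds number of stratified folds (default 10).
#' @param C SVM error penalty (default 1).
#' @param seed integer seed for the fold assignment.
#' @param fold_id optional precomputed fold assignment (overrides `seed`).
#' @return mean held-out accuracy in \[0, 1\].
#' @export
cv_fitness <- function(mask, dataset, folds = 10, C = 1, seed = 1,
                       fold_id = NULL) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("cv_fitness: empty feature mask")
  y <- dataset$labels
  if (length(unique(y)) < 2) stop("cv_fitness: both classes must be present")
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds, seed)
  x <- dataset$values[, mask, drop = FALSE]
  if (anyNA(x)) stop("cv_fitness: dataset contains missing values")
  .dcd_cv_accuracy(x, as.integer(y), as.integer(fold_id),
                   max(fold_id), C, 0.1, 1000L)
}

#' Confusion-count classification metrics
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and F1 `2*Pre*Rec/(Pre+Rec)`. A ratio with zero denominator is
#' reported as 0 and flagged in `undefined`.
#'
#' @param tp,fn,fp,tn non-negative confusion counts (at least one positive).
#' @return list with the four counts, `acc`, `rec`, `pre`, `f1` and
#'   `undefined` (character vector of metrics with zero denominator).
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("at least one count must be positive")
  undefined <- character()
  safe <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); return(0) }
    num / den
  }
  acc <- (tp + tn) / (tp + fn + tn + fp)
  rec <- safe(tp, tp + fn, "rec")
  pre <- safe(tp, tp + fp, "pre")
  f1 <- safe(2 * pre * rec, pre + rec, "f1")
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       acc = acc, rec = rec, pre = pre, f1 = f1, undefined = undefined)
}

#' ROC and precision-recall curves with their areas
#'
#' Sweeps the decision threshold over the distinct classifier scores (higher
#' score = more positive). The ROC runs from (0,0) to (1,1) with AUROC by the
#' trapezoid rule (ties grouped); the precision-recall curve is summarised by
#' step interpolation, AUPRC = sum over threshold steps of
#' (recall gain) x precision.
#'
#' @param scores numeric decision values, one per sample.
#' @param labels 0/1 vector; both classes must be present.
#' @return list with `roc` (data.frame fpr/tpr), `prc` (data.frame
#'   recall/precision), `auroc`, `auprc`.
#' @export
score_curves <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) stop("score_curves: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / pos); fpr <- c(0, fp / neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / pos
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       prc = data.frame(recall = recall, precision = precision),
       auroc = auroc, auprc = auprc)
}

#' Full cross-validated evaluation of a feature subset
#'
#' Trains/tests a linear SVM over stratified folds on the masked columns and
#' aggregates the held-out predictions into confusion counts, the threshold
#' metrics of [confusion_metrics()], and ROC/PRC curves built from the pooled
#' held-out decision values.
#'
#' @inheritParams cv_fitness
#' @return object of class `evaluation_report`: the [confusion_metrics()]
#'   fields plus `roc`, `prc`, `auroc`, `auprc`, `cv_accuracy` (per-fold mean,
#'   the quantity the wrapper optimises) and `folds`.
#' @export
evaluate_subset <- function(mask, dataset, folds = 10, C = 1, seed = 1) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("evaluate_subset: empty feature mask")
  y <- dataset$labels
  if (length(unique(y)) < 2) stop("both classes must be present")
  fold_id <- stratified_folds(y, folds, seed)
  x <- dataset$values[, mask, drop = FALSE]
  pred <- integer(length(y))
  dec <- numeric(length(y))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    m <- svm_linear_fit(x[!te, , drop = FALSE], y[!te], C = C)
    pred[te] <- predict(m, x[te, , drop = FALSE])
    dec[te] <- predict(m, x[te, , drop = FALSE], type = "decision")
    fold_acc[f] <- mean(pred[te] == y[te])
  }
  cm <- confusion_metrics(tp = sum(pred == 1 & y == 1),
                          fn = sum(pred == 0 & y == 1),
                          fp = sum(pred == 1 & y == 0),
                          tn = sum(pred == 0 & y == 0))
  cv <- score_curves(dec, y)
  structure(c(cm, cv, list(cv_accuracy = mean(fold_acc), folds = folds)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("evaluation_report (", x$folds, "-fold cross-validation)\n", sep = "")
  cat(sprintf("  confusion: TP=%d FN=%d FP=%d TN=%d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  acc=%.*f rec=%.*f pre=%.*f f1=%.*f\n",
              digits, x$acc, digits, x$rec, digits, x$pre, digits, x$f1))
  cat(sprintf("  auroc=%.*f auprc=%.*f cv_accuracy=%.*f\n",
              digits, x$auroc, digits, x$auprc, digits, x$cv_accuracy))
  if (length(x$undefined))
    cat("  undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Selection-frequency importance ranking
#'
#' Re-runs the whole selection cascade `n_repeats` times under seeds derived
#' from `seed`; a feature's importance is its selection frequency weighted by
#' each run's final cross-validated fitness, normalised to sum 1 over all
#' features ever selected. This ranking is pipeline plumbing — a stability
#' summary of the stochastic search — not a model-based importance measure.
#'
#' @param dataset a [clinical_dataset()].
#' @param n_repeats number of selection runs (>= 1).
#' @param seed master seed from which the per-run seeds are derived.
#' @param ... further arguments passed to [rqbso()].
#' @return data.frame with columns `feature` and `score`, sorted by
#'   decreasing score (ties broken by feature name).
#' @export
importance_ranking <- function(dataset, n_repeats = 10, seed = 1, ...) {
  stopifnot(n_repeats >= 1)
  seeds <- derive_seeds(seed, n_repeats)
  score <- stats::setNames(numeric(ncol(dataset$values)),
                           colnames(dataset$values))
  for (r in seq_len(n_repeats)) {
    fit <- rqbso(dataset, seed = seeds[r], final_evaluation = FALSE, ...)
    score[fit$selected] <- score[fit$selected] + fit$search_fitness
  }
  if (sum(score) > 0) score <- score / sum(score)
  ord <- order(-score, names(score))
  data.frame(feature = names(score)[ord], score = unname(score[ord]),
             row.names = NULL)
}
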