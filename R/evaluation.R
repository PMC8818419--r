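# Confusion matrices, per-class / overall accuracy, and stratified k-fold
# cross-validation of the RBF classifier.

.as_binary <- function(x, what) {
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% c("normal", "abnormal"))) {
    stop_fmt("%s must be 'normal'/'abnormal'", what)
  }
  factor(x, levels = c("normal", "abnormal"))
}

#' Binary confusion matrix
#'
#' 2 x 2 table of counts with rows = actual class and columns = predicted
#' class, ordered `normal`, `abnormal`, plus row/column/grand totals.
#'
#' @param actual,predicted equal-length vectors of `"normal"`/`"abnormal"`
#'   (character or factor).
#' @return object of class `confusion_matrix`: integer matrix `counts`,
#'   plus `row_totals`, `col_totals`, `total`.
#' @export
confusion <- function(actual, predicted) {
  actual <- .as_binary(actual, "actual")
  predicted <- .as_binary(predicted, "predicted")
  if (length(actual) != length(predicted)) {
    stop_fmt("confusion: length mismatch (%d vs %d)",
             length(actual), length(predicted))
  }
  counts <- table(actual = actual, predicted = predicted)
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(actual = c("normal", "abnormal"),
                                   predicted = c("normal", "abnormal")))
  structure(list(counts = counts, row_totals = rowSums(counts),
                 col_totals = colSums(counts), total = sum(counts)),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param nn,na,an,aa cell counts: actual-normal/predicted-normal,
#'   actual-normal/predicted-abnormal, actual-abnormal/predicted-normal,
#'   actual-abnormal/predicted-abnormal.
#' @return `confusion_matrix`.
#' @export
confusion_from_counts <- function(nn, na, an, aa) {
  counts <- matrix(as.integer(c(nn, an, na, aa)), 2, 2,
                   dimnames = list(actual = c("normal", "abnormal"),
                                   predicted = c("normal", "abnormal")))
  structure(list(counts = counts, row_totals = rowSums(counts),
                 col_totals = colSums(counts), total = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- rbind(cbind(x$counts, Total = x$row_totals),
             Total = c(x$col_totals, x$total))
  cat("          Prediction\n")
  print(m)
  acc <- class_accuracies(x)
  cat(sprintf("normal %.2f%% | abnormal %.2f%% | overall %.2f%%\n",
              acc$normal, acc$abnormal, acc$overall))
  invisible(x)
}

#' Per-class and overall accuracy
#'
#' Normal accuracy = correctly predicted normals / actual normals;
#' abnormal accuracy likewise; overall = trace / grand total.  All three
#' are percentages rounded half-up to two decimals (exact integer
#' arithmetic, so printed-table values reproduce digit for digit).  An
#' empty actual class yields `NA` for that accuracy; the others are still
#' computed.
#'
#' @param cm a `confusion_matrix`.
#' @return list with numeric `normal`, `abnormal`, `overall` (percent).
#' @export
class_accuracies <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cts <- cm$counts
  list(normal = pct_half_up(cts[1, 1], cm$row_totals[[1]]),
       abnormal = pct_half_up(cts[2, 2], cm$row_totals[[2]]),
       overall = pct_half_up(cts[1, 1] + cts[2, 2], cm$total))
}

#' Stratified fold assignment
#'
#' Partitions samples into `k` folds stratified by class: within each
#' class, a seeded random permutation is dealt round-robin, so per-fold
#' class proportions match the global proportions to within one sample and
#' fold sizes differ by at most one.
#'
#' @param labels class labels (`"normal"`/`"abnormal"`).
#' @param k fold count (e.g. 2, 5, 10).
#' @param seed RNG seed.
#' @param stratified set `FALSE` for a plain random (unstratified) split.
#' @return list of class `fold_plan`: `k`, integer `fold` per sample,
#'   `seed`.
#' @export
make_folds <- function(labels, k, seed = 1L, stratified = TRUE) {
  labels <- .as_binary(labels, "labels")
  n <- length(labels)
  if (k < 2 || k > n) stop_fmt("make_folds: k = %d invalid for n = %d", k, n)
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      offset <- 0L
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        if (length(idx) > 0) {
          # continue the round-robin deal across classes so overall fold
          # sizes stay within one of each other
          fold[sample(idx)] <-
            (offset + seq_len(length(idx)) - 1L) %% k + 1L
          offset <- (offset + length(idx)) %% k
        }
      }
    } else {
      fold[sample(n)] <- rep_len(seq_len(k), n)
    }
  })
  structure(list(k = as.integer(k), fold = fold, seed = seed),
            class = "fold_plan")
}

#' Cross-validate the RBF classifier
#'
#' Trains a fresh RBF model per fold on the `k - 1` training folds,
#' evaluates on the held-out fold, and pools the per-fold confusion
#' matrices by summation.  Deterministic under a fixed seed.
#'
#' @param scores numeric score matrix (rows = samples), e.g. PCA scores.
#' @param labels class labels (`"normal"`/`"abnormal"`).
#' @param k fold count.
#' @param H hidden-unit count for [rbf_train()].
#' @param seed RNG seed (fold assignment and per-fold training).
#' @param stratified stratify folds by class (default `TRUE`).
#' @param ... further arguments to [rbf_train()].
#' @return list of class `cv_result`: `folds` (`fold_plan`), `per_fold`
#'   (list of `confusion_matrix`), `pooled` (`confusion_matrix`),
#'   `accuracy` (pooled [class_accuracies()]).
#' @export
cross_validate <- function(scores, labels, k = 5, H = 10, seed = 1L,
                           stratified = TRUE, ...) {
  scores <- as.matrix(scores)
  labels <- .as_binary(labels, "labels")
  plan <- make_folds(labels, k, seed = seed, stratified = stratified)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- plan$fold != f
    te <- !tr
    if (!any(te) || length(unique(labels[te])) < 2 ||
        length(unique(labels[tr])) < 2) {
      stop_fmt("cross_validate: fold %d lacks a class", f)
    }
    model <- rbf_train(scores[tr, , drop = FALSE], labels[tr], H = H,
                       seed = seed, ...)
    pred <- rbf_predict(model, scores[te, , drop = FALSE])
    per_fold[[f]] <- confusion(labels[te], pred)
  }
  pooled_counts <- Reduce(`+`, lapply(per_fold, `[[`, "counts"))
  pooled <- confusion_from_counts(pooled_counts[1, 1], pooled_counts[1, 2],
                                  pooled_counts[2, 1], pooled_counts[2, 2])
  structure(list(folds = plan, per_fold = per_fold, pooled = pooled,
                 accuracy = class_accuracies(pooled)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold cross-validation, n = %d\n",
              x$folds$k, x$pooled$total))
  print(x$pooled)
  invisible(x)
}

#' Holdout evaluation
#'
#' Single train/test split (e.g. 5000/3000): trains one RBF model on a
#' seeded stratified subset of `n_train` samples and evaluates on the
#' rest.
#'
#' @inheritParams cross_validate
#' @param n_train number of training samples.
#' @return list with `model`, `confusion`, `accuracy`.
#' @export
holdout_evaluate <- function(scores, labels, n_train, H = 10, seed = 1L, ...) {
  scores <- as.matrix(scores)
  labels <- .as_binary(labels, "labels")
  n <- length(labels)
  if (n_train < 2 || n_train >= n) {
    stop_fmt("holdout_evaluate: n_train = %d invalid for n = %d", n_train, n)
  }
  tr_idx <- with_seed(seed, {
    idx <- unlist(lapply(levels(labels), function(cl) {
      cls <- which(labels == cl)
      sample(cls, round(length(cls) * n_train / n))
    }))
    idx
  })
  tr <- seq_len(n) %in% tr_idx
  model <- rbf_train(scores[tr, , drop = FALSE], labels[tr], H = H,
                     seed = seed, ...)
  pred <- rbf_predict(model, scores[!tr, , drop = FALSE])
  cm <- confusion(labels[!tr], pred)
  list(model = model, confusion = cm, accuracy = class_accuracies(cm))
}
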