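# Train/test protocol and decoding metrics: stratified 60/40 splits,
# stratified 10-fold cross-validation with a pooled confusion matrix, and
# accuracy / Cohen's kappa / macro precision / macro sensitivity.

#' Stratified train/test split
#'
#' @param x An `mi_recording` or `mi_trials`.
#' @param train_frac Fraction of each class assigned to training (rounded
#'   per class).
#' @param seed Integer seed; the split is reproducible given the seed.
#' @return List with elements `train` and `test` (same class as `x`).
#' @export
split_train_test <- function(x, train_frac = 0.6, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1 ",
         "(both sets must be non-empty)", call. = FALSE)
  labels <- x$labels
  tr_idx <- with_seed(seed, {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(train_frac * length(idx)))
    }))
  })
  tr_idx <- sort(tr_idx)
  if (!length(tr_idx) || length(tr_idx) == length(labels))
    stop("split produced an empty train or test set", call. = FALSE)
  list(train = subset_trials(x, tr_idx),
       test = subset_trials(x, setdiff(seq_along(labels), tr_idx)))
}

#' Decoding metrics from a 2x2 confusion matrix
#'
#' Rows are true classes, columns predicted. Accuracy is the diagonal
#' fraction; Cohen's kappa corrects it by the marginal chance agreement
#' (for balanced true labels `kappa = 2 * accuracy - 1` exactly); precision
#' and sensitivity are macro-averaged over the two classes.
#'
#' @param confusion 2x2 numeric matrix of counts.
#' @return List with `accuracy`, `kappa`, `precision`, `sensitivity`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(2L, 2L)), all(confusion >= 0))
  N <- sum(confusion)
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  acc <- sum(diag(confusion)) / N
  pe <- sum(rowSums(confusion) * colSums(confusion)) / N^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  prec <- diag(confusion) / colSums(confusion)
  sens <- diag(confusion) / rowSums(confusion)
  list(accuracy = acc, kappa = kappa,
       precision = mean(prec, na.rm = TRUE),
       sensitivity = mean(sens, na.rm = TRUE))
}

confusion_matrix <- function(truth, pred) {
  tab <- table(factor(truth, levels = c(1, 2)),
               factor(pred, levels = c(1, 2)))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(true = c("left", "right"),
                              predicted = c("left", "right")))
  m
}

new_decode_result <- function(confusion, per_fold, method, seed) {
  m <- metrics_from_confusion(confusion)
  structure(c(list(confusion = confusion, per_fold = per_fold,
                   method = method, seed = seed), m),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result %s: accuracy %.4f, kappa %.4f, precision %.4f, sensitivity %.4f>\n",
              x$method, x$accuracy, x$kappa, x$precision, x$sensitivity))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation of a decoder
#'
#' Fold confusion matrices are summed and the metrics computed on the pooled
#' confusion, alongside per-fold accuracies.
#'
#' @param fit_fn Function taking a training subset of `x` and returning a
#'   fitted model with a [predict()] method.
#' @param x An `mi_recording` or `mi_trials`.
#' @param folds Number of folds; must not exceed the size of the smaller
#'   class.
#' @param seed Integer seed for the fold assignment.
#' @param method Label stored in the result.
#' @return A `decode_result`.
#' @export
cross_validate <- function(fit_fn, x, folds = 10, seed = 1,
                           method = "decoder") {
  labels <- x$labels
  if (folds > min(table(labels)))
    stop("more folds than trials in the smaller class", call. = FALSE)
  fold <- stratified_folds(labels, folds, seed)
  confusion <- matrix(0L, 2, 2)
  per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    model <- fit_fn(subset_trials(x, tr))
    pred <- predict(model, subset_trials(x, te))
    cm <- confusion_matrix(labels[te], pred)
    confusion <- confusion + cm
    per_fold[f] <- sum(diag(cm)) / sum(cm)
  }
  dimnames(confusion) <- list(true = c("left", "right"),
                              predicted = c("left", "right"))
  new_decode_result(confusion, per_fold, method, seed)
}

#' Evaluate a decoder on a held-out test set
#'
#' @param model A fitted decoder.
#' @param test Test trials.
#' @param method Label stored in the result.
#' @param seed Seed recorded for provenance.
#' @return A `decode_result`.
#' @export
evaluate_holdout <- function(model, test, method = class(model)[1],
                             seed = NA_integer_) {
  pred <- predict(model, test)
  new_decode_result(confusion_matrix(test$labels, pred), per_fold = NULL,
                    method = method, seed = seed)
}

#' Aggregate per-subject decoding results
#'
#' @param results Named list of `decode_result` objects (one per subject).
#' @return List with `summary` (per-subject rows plus a mean row) and
#'   `pooled_confusion` (sum of the subject confusions with its metrics).
#' @export
aggregate_subjects <- function(results) {
  if (!length(results)) stop("no results to aggregate", call. = FALSE)
  ids <- names(results) %||% paste0("sub-", sprintf("%02d", seq_along(results)))
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(subject = ids[i], method = r$method, accuracy = r$accuracy,
               kappa = r$kappa, precision = r$precision,
               sensitivity = r$sensitivity, stringsAsFactors = FALSE)
  }))
  mean_row <- data.frame(subject = "mean", method = rows$method[1],
                         accuracy = mean(rows$accuracy),
                         kappa = mean(rows$kappa),
                         precision = mean(rows$precision),
                         sensitivity = mean(rows$sensitivity),
                         stringsAsFactors = FALSE)
  pooled <- Reduce(`+`, lapply(results, `[[`, "confusion"))
  list(summary = rbind(rows, mean_row),
       pooled_confusion = pooled,
       pooled_metrics = metrics_from_confusion(pooled))
}
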