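# Splits, stratified 10-fold cross-validation, confusion-matrix metrics
# and table-style reporting.

#' Stratified 4:1 train/test split
#'
#' Splits exactly 4:1 within each class (a class of 90 gives 72 train /
#' 18 test; the default 30 x 90 design gives 2,160 / 540 overall),
#' reproducibly for a fixed seed.
#'
#' @param set a [spectrum_set()].
#' @param rng_seed integer seed.
#' @return list with `spectrum_set`s `train` and `test`.
#' @export
split_4to1 <- function(set, rng_seed = 1L) {
  test_idx <- with_seed(rng_seed, {
    unlist(lapply(split(seq_along(set$labels), set$labels), function(ix) {
      n_test <- round(length(ix) / 5)
      sample(ix, n_test)
    }), use.names = FALSE)
  })
  list(train = subset_spectra(set, -test_idx),
       test = subset_spectra(set, test_idx))
}

#' Stratified fold plan
#'
#' Assigns each sample to one of `n_folds` folds, stratified so each
#' class is balanced across folds within one sample (the default 2,700
#' design gives 10 folds of 270, 9 seeds per class per fold).
#'
#' @param set a [spectrum_set()].
#' @param n_folds number of folds.
#' @param rng_seed integer seed.
#' @return an object of class `fold_plan` with fields `n_folds`,
#'   `assignments` (fold index per sample), `stratified`, `rng_seed`.
#' @export
make_folds <- function(set, n_folds = 10L, rng_seed = 1L) {
  n_folds <- as.integer(n_folds)
  n <- length(set$labels)
  if (n_folds < 2L || n_folds > n) stop("n_folds must be in 2..n")
  assignments <- integer(n)
  with_seed(rng_seed, {
    offset <- 0L
    for (ix in split(seq_len(n), set$labels)) {
      folds <- (offset + seq_along(ix) - 1L) %% n_folds + 1L
      assignments[sample(ix)] <- folds
      offset <- offset + length(ix)
    }
  })
  structure(list(n_folds = n_folds, assignments = assignments,
                 stratified = TRUE, rng_seed = as.integer(rng_seed)),
            class = "fold_plan")
}

#' Confusion matrix
#'
#' @param truth,pred integer labels in `1:n_classes`.
#' @param n_classes matrix dimension (default: max label seen).
#' @return `n_classes` x `n_classes` count matrix, rows = truth,
#'   columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, n_classes = max(truth, pred)) {
  if (length(truth) != length(pred)) stop("length mismatch")
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  dimnames(m) <- list(truth = seq_len(n_classes), pred = seq_len(n_classes))
  m
}

#' Metrics from a confusion matrix
#'
#' Multiclass accuracy is `trace / N`; precision, recall and F1 are
#' computed per class one-vs-rest (`TP/(TP+FP)`, `TP/(TP+FN)`, their
#' harmonic mean) and macro-averaged with equal class weight. A class
#' never predicted gets precision 0 (0/0 convention), likewise recall for
#' an absent class.
#'
#' @param confusion square count matrix (rows = truth).
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, and per-class vectors `precision`, `recall`, `f1`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / n,
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1),
       precision = prec, recall = rec, f1 = f1)
}

#' Multiclass cross-entropy loss
#'
#' Mean over samples of the negative log-probability assigned to the true
#' class.
#'
#' @param probabilities N x M matrix of predicted class probabilities.
#' @param labels integer true classes in `1:M`.
#' @return scalar loss (`>= 0`).
#' @export
#' @examples
#' p <- matrix(1 / 30, 4, 30)
#' cross_entropy(p, c(1, 5, 12, 30))  # log(30)
cross_entropy <- function(probabilities, labels) {
  if (nrow(probabilities) != length(labels)) stop("length mismatch")
  -mean(log(probabilities[cbind(seq_along(labels), labels)]))
}

#' Cross-validated evaluation of a model factory
#'
#' For each fold, fits the factory on the remaining folds and predicts the
#' held-out fold. All fitted statistics (transforms, standardizers,
#' covariances) live inside the factory and therefore see training rows
#' only. Per-spectrum smoothing (`preprocess`) is stateless row-wise and
#' applied up front.
#'
#' @param factory `function(train, test)` returning predicted test labels,
#'   or a list with `test_pred` and optionally `train_pred`.
#' @param set a [spectrum_set()].
#' @param plan a [make_folds()] plan.
#' @param preprocess optional [preprocess_config()] applied to every
#'   spectrum before fitting.
#' @param n_classes confusion-matrix dimension.
#' @return an object of class `eval_report`: per-fold metrics, pooled
#'   confusion matrix, and per-metric mean with `(max - mean)` /
#'   `(mean - min)` deviations; `time_ms` is the mean per-sample wall time
#'   of a fold's fit+predict divided over its test rows.
#' @export
cross_validate <- function(factory, set, plan, preprocess = NULL,
                           n_classes = max(set$labels)) {
  if (!is.null(preprocess)) set <- apply_preprocess(preprocess, set)
  folds <- seq_len(plan$n_folds)
  per_fold <- vector("list", plan$n_folds)
  confusion <- matrix(0L, n_classes, n_classes)
  for (f in folds) {
    hold <- plan$assignments == f
    train <- subset_spectra(set, !hold)
    test <- subset_spectra(set, hold)
    t0 <- proc.time()[["elapsed"]]
    res <- factory(train, test)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (!is.list(res)) res <- list(test_pred = res)
    cm <- confusion_matrix(test$labels, res$test_pred, n_classes)
    confusion <- confusion + cm
    m <- metrics_from_confusion(cm)
    per_fold[[f]] <- data.frame(
      fold = f, accuracy = m$accuracy,
      train_accuracy = if (!is.null(res$train_pred))
        mean(res$train_pred == train$labels) else NA_real_,
      macro_precision = m$macro_precision,
      macro_recall = m$macro_recall, macro_f1 = m$macro_f1,
      time_ms = 1000 * elapsed / nrow(test$spectra))
  }
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("accuracy", "train_accuracy", "macro_precision",
               "macro_recall", "macro_f1", "time_ms")
  agg <- lapply(metrics, function(mn) {
    v <- per_fold[[mn]]
    if (all(is.na(v))) return(list(mean = NA_real_, plus_dev = NA_real_,
                                   minus_dev = NA_real_))
    list(mean = mean(v), plus_dev = max(v) - mean(v),
         minus_dev = mean(v) - min(v))
  })
  names(agg) <- metrics
  structure(list(per_fold = per_fold, aggregate = agg,
                 confusion = confusion, n_folds = plan$n_folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<eval_report> %d folds | accuracy %.2f%% (+%.2f/-%.2f) | macro-F1 %.2f%%\n",
    x$n_folds, 100 * a$accuracy$mean, 100 * a$accuracy$plus_dev,
    100 * a$accuracy$minus_dev, 100 * a$macro_f1$mean))
  invisible(x)
}

#' One table row from an evaluation report
#'
#' Formats the aggregate of a [cross_validate()] report the way the
#' study's results tables are laid out: mean with max/min deviations for
#' training accuracy, test accuracy, macro precision/recall/F1, and mean
#' per-sample inference time.
#'
#' @param report an `eval_report`.
#' @return one-row data frame of formatted strings.
#' @export
format_report_row <- function(report) {
  a <- report$aggregate
  pct <- function(m) {
    if (is.na(m$mean)) return("-")
    sprintf("%.2f%% +%.2f%%/-%.2f%%", 100 * m$mean, 100 * m$plus_dev,
            100 * m$minus_dev)
  }
  data.frame(train = pct(a$train_accuracy), test = pct(a$accuracy),
             precision = pct(a$macro_precision), recall = pct(a$macro_recall),
             f1 = pct(a$macro_f1),
             time = sprintf("%.2fms", a$time_ms$mean))
}

#' Metrics JSON export
#'
#' Writes the aggregate and per-fold metrics of an [cross_validate()]
#' report as JSON (`metric -> {mean, plus_dev, minus_dev, per_fold[]}`),
#' and optionally the pooled confusion matrix as CSV.
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @param confusion_csv optional CSV path for the confusion matrix.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, confusion_csv = NULL) {
  out <- lapply(names(report$aggregate), function(mn) {
    c(report$aggregate[[mn]], list(per_fold = report$per_fold[[mn]]))
  })
  names(out) <- names(report$aggregate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(confusion_csv))
    utils::write.csv(as.data.frame(report$confusion), confusion_csv,
                     row.names = FALSE)
  invisible(path)
}
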