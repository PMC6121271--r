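#' Stratified k-fold split
#'
#' Partitions a labeled dataset into k folds, stratified by class so every
#' fold keeps the class proportions of the whole dataset. The same seed
#' always produces the same folds.
#'
#' @param dataset A [wv_dataset].
#' @param k Number of folds (default 10).
#' @param seed Shuffle seed.
#' @return List of k integer vectors of instance indices; disjoint, and
#'   their union is `seq_along(dataset$instances)`.
#' @export
kfold_split <- function(dataset, k = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "wv_dataset"))
  k <- as.integer(k)
  n <- length(dataset$instances)
  if (k < 2L) stop("k must be at least 2 (k = 1 leaves no held-out data)", call. = FALSE)
  if (k > n) stop("k exceeds the number of instances", call. = FALSE)
  labels <- dataset_labels(dataset)
  set.seed(as.integer(seed))
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    idx <- which(labels %in% cl)
    idx <- idx[sample.int(length(idx))]
    assign_to <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  }
  lapply(folds, sort)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F1 = 2 * precision * recall / (precision + recall)` (the harmonic
#' mean). Any 0/0 denominator yields 0, with a warning.
#'
#' @param tp,fp,fn Non-negative true-positive, false-positive and
#'   false-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
classification_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is 0/0; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 is 0/0; reporting 0", call. = FALSE)
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' k-fold cross-validation of the wave-embedding classifier
#'
#' For each fold: fit the quantizer, the CBOW embeddings and the class
#' models on the training portion only, then classify the held-out fold.
#' No information from the test fold enters any fitting step. Metrics are
#' computed per fold and pooled over the summed confusion counts; F1 is
#' the primary metric (accuracy is reported but is vulnerable to the
#' accuracy paradox under class imbalance).
#'
#' @param dataset A labeled [wv_dataset] with at least 2 classes.
#' @param k Number of folds.
#' @param seed Seed controlling both the fold split and embedding
#'   initialization.
#' @param positive_class Class treated as "positive" for
#'   precision/recall/F1; defaults to the first class in the dataset's
#'   class set (by convention the disease class).
#' @param ... Model parameters passed to [wave2vec()] (`base_n`, `window`,
#'   `dim`, `epochs`, ...).
#' @return Object of class `wv_eval`: list with `folds` (data frame of
#'   per-fold counts and metrics), `pooled` (named vector), `predictions`
#'   (data frame: instance_id, fold, truth, predicted), `positive_class`,
#'   `config`.
#' @export
run_cv <- function(dataset, k = 10L, seed = 1L, positive_class = NULL, ...) {
  stopifnot(inherits(dataset, "wv_dataset"))
  labels <- dataset_labels(dataset)
  if (anyNA(labels)) stop("cross-validation needs a fully labeled dataset", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("dataset must contain at least 2 classes", call. = FALSE)
  if (is.null(positive_class)) positive_class <- dataset$classes[1]
  if (!positive_class %in% classes) {
    stop("positive_class not present in the data: ", positive_class, call. = FALSE)
  }
  folds <- kfold_split(dataset, k = k, seed = seed)
  for (f in seq_along(folds)) {
    train_labels <- labels[-folds[[f]]]
    if (!all(classes %in% train_labels)) {
      stop("stratification error: fold ", f, " training data misses a class",
           call. = FALSE)
    }
  }
  fold_rows <- vector("list", length(folds))
  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    fit <- wave2vec(dataset_subset(dataset, -test_idx), seed = seed, ...)
    predicted <- predict(fit, dataset_subset(dataset, test_idx))
    truth <- labels[test_idx]
    tp <- sum(predicted == positive_class & truth == positive_class)
    fp <- sum(predicted == positive_class & truth != positive_class)
    fn <- sum(predicted != positive_class & truth == positive_class)
    tn <- sum(predicted != positive_class & truth != positive_class)
    m <- suppressWarnings(classification_metrics(tp, fp, fn))
    fold_rows[[f]] <- data.frame(fold = f, tp = tp, fp = fp, fn = fn, tn = tn,
                                 precision = m[["precision"]],
                                 recall = m[["recall"]], f1 = m[["f1"]],
                                 accuracy = (tp + tn) / length(test_idx))
    preds[[f]] <- data.frame(instance_id = vapply(dataset$instances[test_idx],
                                                  `[[`, character(1), "instance_id"),
                             fold = f, truth = truth, predicted = predicted)
  }
  folds_df <- do.call(rbind, fold_rows)
  tp <- sum(folds_df$tp); fp <- sum(folds_df$fp)
  fn <- sum(folds_df$fn); tn <- sum(folds_df$tn)
  pm <- suppressWarnings(classification_metrics(tp, fp, fn))
  pooled <- c(tp = tp, fp = fp, fn = fn, tn = tn, pm,
              accuracy = (tp + tn) / (tp + fp + fn + tn))
  structure(
    list(folds = folds_df, pooled = pooled,
         predictions = do.call(rbind, preds),
         positive_class = positive_class,
         config = c(list(k = k, seed = seed), list(...))),
    class = "wv_eval"
  )
}

#' @export
print.wv_eval <- function(x, ...) {
  cat(sprintf("k-fold cross-validation (k=%d, positive class: %s)\n",
              nrow(x$folds), x$positive_class))
  cat(sprintf("Pooled: precision %.4f, recall %.4f, F1 %.4f, accuracy %.4f\n",
              x$pooled[["precision"]], x$pooled[["recall"]],
              x$pooled[["f1"]], x$pooled[["accuracy"]]))
  cat(sprintf("Counts: tp %d fp %d fn %d tn %d\n",
              x$pooled[["tp"]], x$pooled[["fp"]], x$pooled[["fn"]],
              x$pooled[["tn"]]))
  invisible(x)
}

#' Default encoding-resolution grid
#'
#' The 13 encoding base numbers swept when searching for the optimal
#' quantization degree.
#'
#' @return Integer vector `c(8, 16, 32, 48, 64, 96, 128, 192, 256, 384,
#'   512, 768, 1024)`.
#' @export
default_base_n_grid <- function() {
  c(8L, 16L, 32L, 48L, 64L, 96L, 128L, 192L, 256L, 384L, 512L, 768L, 1024L)
}

#' Sweep the encoding base number
#'
#' Runs [run_cv()] once per encoding base number and collects pooled
#' precision, recall and F1 — the data behind a resolution-vs-performance
#' bar chart. Coarse alphabets lose signal; very fine ones erode the
#' benefit of encoding.
#'
#' @param dataset A labeled [wv_dataset].
#' @param base_n_list Base numbers to try; defaults to
#'   [default_base_n_grid()].
#' @param ... Passed to [run_cv()] (`k`, `seed`, model parameters...).
#' @return Data frame with columns `base_n`, `alphabet_size`, `precision`,
#'   `recall`, `f1`, `accuracy`.
#' @export
sweep_base_n <- function(dataset, base_n_list = default_base_n_grid(), ...) {
  if (!length(base_n_list)) stop("base_n_list must be non-empty", call. = FALSE)
  rows <- lapply(base_n_list, function(bn) {
    ev <- run_cv(dataset, base_n = bn, ...)
    data.frame(base_n = bn,
               alphabet_size = bn - 1L,
               precision = ev$pooled[["precision"]],
               recall = ev$pooled[["recall"]],
               f1 = ev$pooled[["f1"]],
               accuracy = ev$pooled[["accuracy"]])
  })
  do.call(rbind, rows)
}
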