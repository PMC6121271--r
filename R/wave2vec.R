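#' Fit a wave-embedding signal classifier
#'
#' The full training pipeline on a labeled dataset of raw signals:
#' (1) delta-encode every instance and fit a Gaussian quantizer with a
#' `base_n` symbol alphabet on the pooled training deltas; (2) encode all
#' instances into symbol sequences; (3) train CBOW wave embeddings on the
#' encoded corpus (unsupervised — labels are not used here); (4) build one
#' class model per class as the vector sum of that class's sequence
#' vectors. Prediction assigns the class whose model has the largest
#' cosine similarity to a new signal's sequence vector.
#'
#' @param data A [wv_dataset] whose instances carry labels, or a list of
#'   labeled [wv_signal] objects.
#' @param base_n Even encoding base number (alphabet resolution),
#'   default 64.
#' @param clip_z Noise clip bound in standard deviations (default 2).
#' @param window CBOW window parameter (default 10 context symbols per
#'   side; see [make_training_windows()]).
#' @param dim Embedding dimension (default 50).
#' @param epochs CBOW training passes (default 3).
#' @param learning_rate Initial SGD step size.
#' @param min_frequency Vocabulary filter.
#' @param target_rate_hz Optional decimation target applied before
#'   encoding.
#' @param seed Seed for embedding initialization.
#' @return An object of class `wave2vec`: list with `quantizer`, `table`
#'   (the [wv_vectable]), `models` (per-class [build_class_model()]
#'   objects), `classes`, `config`, `call`.
#' @examples
#' cfg <- synth_config(n_per_class = 10, length_samples = 64)
#' ds <- generate_dataset(cfg, seed = 1)
#' fit <- wave2vec(ds, base_n = 8, dim = 8, epochs = 2, seed = 1)
#' predict(fit, dataset_subset(ds, 1:2))
#' @export
wave2vec <- function(data, base_n = 64L, clip_z = 2.0, window = 10L,
                     dim = 50L, epochs = 3L, learning_rate = 0.05,
                     min_frequency = 1L, target_rate_hz = NULL, seed = 1L) {
  if (!inherits(data, "wv_dataset")) data <- wv_dataset(data)
  labels <- dataset_labels(data)
  if (anyNA(labels)) stop("all training instances must be labeled", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  quantizer <- fit_quantizer(dataset_deltas(data, target_rate_hz),
                             base_n = base_n, clip_z = clip_z)
  corpus <- encode_dataset(data, quantizer, target_rate_hz = target_rate_hz)
  table <- train_cbow(corpus, window = window, dim = dim, epochs = epochs,
                      learning_rate = learning_rate,
                      min_frequency = min_frequency, seed = seed)
  classes <- sort(unique(labels))
  models <- lapply(classes, function(cl) {
    build_class_model(corpus[labels == cl], table, label = cl)
  })
  structure(
    list(quantizer = quantizer, table = table, models = models,
         classes = classes,
         config = list(base_n = base_n, clip_z = clip_z, window = window,
                       dim = dim, epochs = epochs,
                       learning_rate = learning_rate,
                       min_frequency = min_frequency,
                       target_rate_hz = target_rate_hz, seed = seed),
         n_training = length(data$instances),
         call = match.call()),
    class = "wave2vec"
  )
}

#' @export
print.wave2vec <- function(x, ...) {
  cat("Wave-embedding signal classifier\n\n")
  cat("Call:\n  ", deparse(x$call), "\n\n", sep = "")
  cat(sprintf("Encoding: base_n=%d (%d symbols), clip_z=%g\n",
              x$config$base_n, length(x$quantizer$alphabet), x$config$clip_z))
  cat(sprintf("Embedding: dim=%d, window=%d, epochs=%d, V=%d\n",
              x$config$dim, x$config$window, x$config$epochs,
              nrow(x$table$vectors)))
  cat(sprintf("Classes (%d training instances): %s\n", x$n_training,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.wave2vec <- function(object, ...) {
  loss <- attr(object$table, "epoch_loss")
  model_norms <- vapply(object$models, function(m) sqrt(sum(m$model_vector^2)),
                        numeric(1))
  names(model_norms) <- object$classes
  out <- list(
    config = object$config,
    classes = object$classes,
    n_training = object$n_training,
    vocab_size = nrow(object$table$vectors),
    epoch_loss = loss,
    model_norms = model_norms,
    model_cosine = if (length(object$models) == 2L) {
      cosine_similarity(object$models[[1]]$model_vector,
                        object$models[[2]]$model_vector)
    } else NA_real_
  )
  class(out) <- "summary.wave2vec"
  out
}

#' @export
print.summary.wave2vec <- function(x, ...) {
  cat("Wave-embedding signal classifier\n")
  cat(sprintf("  %d training instances, %d classes, vocabulary %d\n",
              x$n_training, length(x$classes), x$vocab_size))
  cat("  CBOW mean cross-entropy by epoch:",
      paste(sprintf("%.4f", x$epoch_loss), collapse = " "), "\n")
  cat("  Class model norms:\n")
  for (cl in names(x$model_norms)) {
    cat(sprintf("    %-12s %.4g\n", cl, x$model_norms[[cl]]))
  }
  if (!is.na(x$model_cosine)) {
    cat(sprintf("  Cosine between class models: %.4f\n", x$model_cosine))
  }
  invisible(x)
}

#' Wave vectors of a fitted classifier
#' @param object A `wave2vec` fit.
#' @param ... Unused.
#' @return The V x N embedding matrix (rows named by symbol).
#' @export
coef.wave2vec <- function(object, ...) {
  object$table$vectors
}

#' Classify new signals with a fitted model
#'
#' New instances are encoded with the training-time quantizer (no
#' refitting, so nothing leaks from test data) and scored by cosine
#' similarity against every class model.
#'
#' @param object A `wave2vec` fit.
#' @param newdata A [wv_dataset], a list of [wv_signal]s, or a list of
#'   already-encoded [wv_symseq]s.
#' @param type `"class"` for the winning labels, `"scores"` for the full
#'   similarity matrix (instances x classes).
#' @param ... Unused.
#' @return Character vector of labels, or a numeric score matrix.
#' @export
predict.wave2vec <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  corpus <- if (is_corpus(newdata)) {
    newdata
  } else {
    if (!inherits(newdata, "wv_dataset")) newdata <- wv_dataset(newdata)
    encode_dataset(newdata, object$quantizer,
                   target_rate_hz = object$config$target_rate_hz)
  }
  res <- lapply(corpus, classify, models = object$models, table = object$table)
  if (type == "class") {
    out <- vapply(res, `[[`, character(1), "label")
  } else {
    out <- do.call(rbind, lapply(res, `[[`, "scores"))
  }
  ids <- vapply(corpus, `[[`, character(1), "instance_id")
  if (is.matrix(out)) rownames(out) <- ids else names(out) <- ids
  out
}

#' Heat map of a fitted model's symbol similarity matrix
#'
#' Plots the pairwise cosine similarities between all alphabet-symbol wave
#' vectors, axes ordered from the strongest falls (bottom left) to the
#' strongest rises (top right), on a blue-to-red scale.
#'
#' @param x A `wave2vec` fit.
#' @param ... Passed on to [render_heatmap()]'s plotting core.
#' @return The [similarity_matrix()] invisibly.
#' @export
plot.wave2vec <- function(x, ...) {
  m <- similarity_matrix(x$table,
                         ordering = intersect(x$quantizer$alphabet,
                                              rownames(x$table$vectors)))
  draw_heatmap(m, limits = c(-1, 1), ...)
  invisible(m)
}

#' Residual-style diagnostics: per-instance classification margins
#'
#' For each training (or new) instance, the difference between its best
#' and second-best class-model cosine score. Small or negative margins for
#' the true class mark instances the model barely separates.
#'
#' @param object A `wave2vec` fit.
#' @param newdata Data to score (see [predict.wave2vec()]).
#' @return Data frame with `instance_id`, `predicted`, `margin`.
#' @export
classification_margins <- function(object, newdata) {
  scores <- predict(object, newdata, type = "scores")
  ord <- t(apply(scores, 1, sort, decreasing = TRUE))
  data.frame(
    instance_id = rownames(scores),
    predicted = colnames(scores)[apply(scores, 1, which.max)],
    margin = ord[, 1] - ord[, 2]
  )
}
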