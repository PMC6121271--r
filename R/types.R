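#' Construct a raw signal instance
#'
#' A `wv_signal` holds one channel's recording of one trial: an ordered
#' vector of real amplitudes (conventionally microvolts) plus the sampling
#' rate and an optional class label. One 1 s EEG trial at 256 Hz is one
#' instance.
#'
#' @param samples Numeric vector of amplitudes; must be non-empty and finite.
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param instance_id Identifier string, unique within a dataset.
#' @param channel Channel name (e.g. `"CP6"`), or `NA`.
#' @param label Optional class label string, or `NA` for unlabeled data.
#' @return An object of class `wv_signal`.
#' @examples
#' s <- wv_signal(sin(seq(0, 2 * pi, length.out = 256)), 256, "trial1")
#' length(s$samples)
#' @export
wv_signal <- function(samples, sampling_rate_hz, instance_id = "signal",
                      channel = NA_character_, label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("empty signal: no samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal contains non-finite samples", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number", call. = FALSE)
  }
  structure(
    list(
      instance_id = as.character(instance_id),
      channel = as.character(channel),
      samples = samples,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      label = as.character(label)
    ),
    class = "wv_signal"
  )
}

#' @export
print.wv_signal <- function(x, ...) {
  cat(sprintf(
    "<wv_signal> %s  channel=%s  n=%d  rate=%g Hz  label=%s\n",
    x$instance_id, x$channel, length(x$samples), x$sampling_rate_hz, x$label
  ))
  invisible(x)
}

#' Construct a labeled dataset of signal instances
#'
#' @param instances List of [wv_signal] objects with unique `instance_id`s.
#' @param classes Character vector of class labels; defaults to the labels
#'   observed on the instances.
#' @return An object of class `wv_dataset`.
#' @export
wv_dataset <- function(instances, classes = NULL) {
  if (!is.list(instances) || !all(vapply(instances, inherits, logical(1), "wv_signal"))) {
    stop("instances must be a list of wv_signal objects", call. = FALSE)
  }
  ids <- vapply(instances, function(s) s$instance_id, character(1))
  if (anyDuplicated(ids)) {
    stop("instance_ids are not unique: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  labels <- vapply(instances, function(s) s$label, character(1))
  if (is.null(classes)) classes <- sort(unique(labels[!is.na(labels)]))
  bad <- setdiff(labels[!is.na(labels)], classes)
  if (length(bad)) {
    stop("label not in class set: ", bad[1], call. = FALSE)
  }
  structure(
    list(instances = instances, classes = as.character(classes)),
    class = "wv_dataset"
  )
}

#' @export
print.wv_dataset <- function(x, ...) {
  labels <- dataset_labels(x)
  cat(sprintf("<wv_dataset> %d instances, classes: %s\n",
              length(x$instances), paste(x$classes, collapse = ", ")))
  print(table(labels, useNA = "ifany"))
  invisible(x)
}

#' @export
length.wv_dataset <- function(x) length(x$instances)

#' Labels of a dataset's instances, in instance order
#' @param dataset A [wv_dataset].
#' @return Character vector (possibly with `NA` for unlabeled instances).
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$instances, function(s) s$label, character(1))
}

#' Subset a dataset by instance index
#' @param dataset A [wv_dataset].
#' @param idx Integer or logical index into the instance list.
#' @return A [wv_dataset] with the selected instances and the same class set.
#' @export
dataset_subset <- function(dataset, idx) {
  wv_dataset(dataset$instances[idx], classes = dataset$classes)
}

#' Construct a symbol sequence
#'
#' The encoded form of one signal instance: an ordered vector of alphabet
#' tokens, one per encoded wavelet (inter-sample amplitude change in delta
#' mode, one sample in amplitude mode).
#'
#' @param tokens Character vector of symbols.
#' @param instance_id Identifier of the source instance.
#' @param label Optional class label.
#' @return An object of class `wv_symseq`.
#' @export
wv_symseq <- function(tokens, instance_id = "seq", label = NA_character_) {
  structure(
    list(
      instance_id = as.character(instance_id),
      tokens = as.character(tokens),
      label = as.character(label)
    ),
    class = "wv_symseq"
  )
}

#' @export
print.wv_symseq <- function(x, n = 12L, ...) {
  shown <- paste(head(x$tokens, n), collapse = " ")
  if (length(x$tokens) > n) shown <- paste(shown, "...")
  cat(sprintf("<wv_symseq> %s (label=%s, %d tokens): %s\n",
              x$instance_id, x$label, length(x$tokens), shown))
  invisible(x)
}

is_corpus <- function(x) {
  is.list(x) && all(vapply(x, inherits, logical(1), "wv_symseq"))
}
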