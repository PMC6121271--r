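#' Vector representation of a symbol sequence
#'
#' Sums the wave vectors of all tokens in the sequence. Tokens absent from
#' the table (out-of-vocabulary) are skipped; a sequence with no known
#' token yields the zero vector, flagged degenerate rather than silently
#' classified.
#'
#' @param seq A [wv_symseq].
#' @param table A [wv_vectable].
#' @return Numeric vector of length N with attribute `degenerate`
#'   (`TRUE` if no token was found in the table).
#' @export
sequence_vector <- function(seq, table) {
  stopifnot(inherits(seq, "wv_symseq"), inherits(table, "wv_vectable"))
  idx <- match(seq$tokens, rownames(table$vectors))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    v <- numeric(ncol(table$vectors))
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  v <- colSums(table$vectors[idx, , drop = FALSE])
  attr(v, "degenerate") <- FALSE
  v
}

#' Build a class model by vector summation
#'
#' A class model is the sum of the sequence vectors of all training
#' sequences of that class. Only the direction of the model vector
#' matters for classification (cosine similarity is scale invariant), so
#' summing and averaging give identical decisions.
#'
#' @param seqs Non-empty list of [wv_symseq] belonging to one class.
#' @param table A [wv_vectable].
#' @param label Class label for the model.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return Object of class `wv_classmodel`: list with `label`,
#'   `model_vector`, `n_training_sequences`.
#' @export
build_class_model <- function(seqs, table, label, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is_corpus(seqs))
  if (length(seqs) == 0L) stop("cannot build a class model from zero sequences", call. = FALSE)
  vecs <- lapply(seqs, sequence_vector, table = table)
  v <- Reduce(`+`, vecs)
  if (aggregate == "mean") v <- v / length(seqs)
  attributes(v) <- NULL
  structure(
    list(label = as.character(label), model_vector = v,
         n_training_sequences = length(seqs)),
    class = "wv_classmodel"
  )
}

#' @export
print.wv_classmodel <- function(x, ...) {
  cat(sprintf("<wv_classmodel> %s (n=%d, |v|=%.4g)\n",
              x$label, x$n_training_sequences, sqrt(sum(x$model_vector^2))))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' `A . B / (||A|| ||B||)`: 1 for identical directions, 0 for orthogonal,
#' -1 for opposite directions. Undefined (an error) for a zero vector.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("undefined similarity: zero vector", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Classify a symbol sequence against class models
#'
#' Computes the sequence's wave vector and returns the label of the class
#' model with the largest cosine similarity to it, together with all
#' scores. Exact ties go to the earlier model in the list.
#'
#' @param seq A [wv_symseq].
#' @param models List of at least two [build_class_model()] objects.
#' @param table The shared [wv_vectable].
#' @return List with `label` and named numeric `scores`.
#' @export
classify <- function(seq, models, table) {
  if (length(models) < 2L) stop("need at least 2 class models", call. = FALSE)
  v <- sequence_vector(seq, table)
  if (isTRUE(attr(v, "degenerate"))) {
    stop("unclassifiable: sequence has no in-vocabulary token", call. = FALSE)
  }
  scores <- vapply(models, function(m) cosine_similarity(v, m$model_vector),
                   numeric(1))
  names(scores) <- vapply(models, `[[`, character(1), "label")
  list(label = names(scores)[which.max(scores)], scores = scores)
}

ngrams_of <- function(tokens, n) {
  len <- length(tokens)
  if (len < n) return(character(0))
  if (n == 1L) return(tokens)
  m <- vapply(seq_len(len - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = " ")
  }, character(1))
  m
}

#' Fit pattern statistics for the pattern-probability classifier
#'
#' Counts every contiguous token n-gram of length 1..`max_pattern_len` in
#' the labeled corpus. For a pattern and class c, `L` is the number of
#' occurrences of the pattern in training sequences of class c, and `G(N)`
#' is the total number of pattern occurrences of length N across the whole
#' training corpus, so `p(c | pattern) = L / G(N)`. The pattern weight
#' `S(N) = N` gives longer patterns proportionally more influence.
#'
#' @param corpus List of labeled [wv_symseq].
#' @param max_pattern_len Longest n-gram counted.
#' @return Object of class `wv_patternstats`: `L` (environment mapping
#'   pattern string to named per-class counts), `G` (named numeric by
#'   length), `classes`, `max_pattern_len`.
#' @export
fit_pattern_stats <- function(corpus, max_pattern_len = 2L) {
  stopifnot(is_corpus(corpus))
  max_pattern_len <- as.integer(max_pattern_len)
  if (max_pattern_len < 1L) stop("max_pattern_len must be >= 1", call. = FALSE)
  labels <- vapply(corpus, `[[`, character(1), "label")
  if (anyNA(labels)) stop("pattern statistics need a fully labeled corpus", call. = FALSE)
  classes <- sort(unique(labels))
  L <- new.env(parent = emptyenv())
  G <- stats::setNames(numeric(max_pattern_len), seq_len(max_pattern_len))
  for (k in seq_along(corpus)) {
    toks <- corpus[[k]]$tokens
    cls <- labels[k]
    for (n in seq_len(max_pattern_len)) {
      pats <- ngrams_of(toks, n)
      G[n] <- G[n] + length(pats)
      for (p in pats) {
        cur <- L[[p]]
        if (is.null(cur)) cur <- stats::setNames(numeric(length(classes)), classes)
        cur[cls] <- cur[cls] + 1
        L[[p]] <- cur
      }
    }
  }
  structure(
    list(L = L, G = G, classes = classes, max_pattern_len = max_pattern_len),
    class = "wv_patternstats"
  )
}

#' Class score of a sequence under the pattern-probability model
#'
#' Sums `O * S * p(c | pattern)` over the distinct patterns of length
#' 1..`max_pattern_len` occurring in the sequence, divided by the token
#' count n of the sequence. `O` is the pattern's occurrence count in the
#' sequence and `S(N) = N` its length weight. The score is non-negative
#' and zero exactly when no pattern of the sequence was ever seen in
#' class c.
#'
#' @param seq A [wv_symseq] with at least one token.
#' @param stats A [fit_pattern_stats()] object.
#' @param class Class label.
#' @return Non-negative numeric score.
#' @export
sequence_class_prob <- function(seq, stats, class) {
  stopifnot(inherits(seq, "wv_symseq"), inherits(stats, "wv_patternstats"))
  toks <- seq$tokens
  if (length(toks) == 0L) stop("empty sequence has no class score", call. = FALSE)
  total <- 0
  for (n in seq_len(stats$max_pattern_len)) {
    pats <- ngrams_of(toks, n)
    if (!length(pats)) next
    occ <- table(pats)
    for (p in names(occ)) {
      cnt <- stats$L[[p]]
      if (is.null(cnt)) next
      l <- if (class %in% names(cnt)) cnt[[class]] else 0
      total <- total + as.numeric(occ[[p]]) * n * (l / stats$G[[n]])
    }
  }
  total / length(toks)
}

#' Classify a sequence by pattern probabilities
#'
#' The baseline sequence classifier: argmax over classes of
#' [sequence_class_prob()], ties broken by lexical class order.
#'
#' @inheritParams sequence_class_prob
#' @return The winning class label.
#' @export
classify_by_patterns <- function(seq, stats) {
  if (length(stats$classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  scores <- vapply(stats$classes, function(cl) sequence_class_prob(seq, stats, cl),
                   numeric(1))
  if (all(scores == 0)) {
    stop("unclassifiable: no pattern of the sequence was seen in training",
         call. = FALSE)
  }
  stats$classes[which.max(scores)]  # classes sorted => lexical tie-break
}
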