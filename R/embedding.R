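#' Build a vocabulary from a symbol corpus
#'
#' Counts token occurrences over the corpus and retains every token seen at
#' least `min_frequency` times. Dropped tokens are skipped entirely during
#' window construction and training.
#'
#' The retained symbols are ordered lexicographically. This canonical
#' ordering means two corpora sharing the same symbols assign them the
#' same indices, so embeddings trained from the same seed start from the
#' same per-symbol initialization — which keeps per-class similarity
#' matrices comparable.
#'
#' @param corpus List of [wv_symseq].
#' @param min_frequency Minimum occurrence count for a token to be kept.
#' @return An object of class `wv_vocab`: list with `symbols` (sorted),
#'   `counts` (named integer vector over retained symbols),
#'   `min_frequency`.
#' @export
build_vocab <- function(corpus, min_frequency = 1L) {
  stopifnot(is_corpus(corpus), length(corpus) > 0L)
  tokens <- unlist(lapply(corpus, `[[`, "tokens"), use.names = FALSE)
  if (length(tokens) == 0L) stop("empty vocabulary: corpus has no tokens", call. = FALSE)
  counts <- table(tokens)
  keep <- counts >= min_frequency
  if (!any(keep)) {
    stop("empty vocabulary: no token reaches min_frequency = ", min_frequency,
         call. = FALSE)
  }
  counts <- counts[keep]
  symbols <- sort(names(counts))
  structure(
    list(symbols = symbols,
         counts = stats::setNames(as.integer(counts), names(counts))[symbols],
         min_frequency = as.integer(min_frequency)),
    class = "wv_vocab"
  )
}

#' @export
print.wv_vocab <- function(x, ...) {
  cat(sprintf("<wv_vocab> V=%d (min_frequency=%d)\n",
              length(x$symbols), x$min_frequency))
  invisible(x)
}

context_per_side <- function(window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  # odd window = total sliding-window length t (center target, (t-1)/2 per
  # side); an even window is taken directly as the context size per side
  if (window %% 2L == 1L) (window - 1L) %/% 2L else window
}

#' Enumerate CBOW training windows over one sequence
#'
#' Slides a window one symbol at a time; the center symbol is the
#' prediction target and up to `(t-1)/2` symbols on each side are its
#' context, truncated at the sequence boundaries (no padding). Tokens
#' outside the vocabulary are removed before windowing.
#'
#' @param seq A [wv_symseq].
#' @param window Window parameter: an odd value is the total window length
#'   t; an even value is interpreted as the context size per side.
#' @param vocab Optional `wv_vocab`; tokens not in it are skipped.
#' @return List of `list(context = character, target = character)`, one per
#'   retained token position (positions with no context, e.g. a
#'   single-token sequence, are omitted).
#' @export
make_training_windows <- function(seq, window, vocab = NULL) {
  stopifnot(inherits(seq, "wv_symseq"))
  cs <- context_per_side(window)
  toks <- seq$tokens
  if (!is.null(vocab)) toks <- toks[toks %in% vocab$symbols]
  n <- length(toks)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- toks[setdiff(max(1L, i - cs):min(n, i + cs), i)]
    out[[i]] <- list(context = ctx, target = toks[i])
  }
  out[vapply(out, function(w) length(w$context) > 0L, logical(1))]
}

#' Construct a wave vector table
#'
#' @param vectors Numeric matrix, one row per token (rownames are the
#'   tokens), one column per embedding dimension.
#' @param vocab Optional `wv_vocab` the table was trained over.
#' @param config Optional list of training parameters, kept for
#'   provenance.
#' @return An object of class `wv_vectable`.
#' @export
wv_vectable <- function(vectors, vocab = NULL, config = NULL) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (!all(is.finite(vectors))) stop("vector table contains non-finite values", call. = FALSE)
  structure(list(vectors = vectors, vocab = vocab, config = config),
            class = "wv_vectable")
}

#' @export
print.wv_vectable <- function(x, ...) {
  cat(sprintf("<wv_vectable> V=%d tokens, N=%d dimensions\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Look up the wave vector of a token
#' @param table A [wv_vectable].
#' @param token Token string.
#' @return Numeric vector of length N.
#' @export
wave_vector <- function(table, token) {
  stopifnot(inherits(table, "wv_vectable"))
  i <- match(token, rownames(table$vectors))
  if (is.na(i)) stop("token not in vector table: ", token, call. = FALSE)
  table$vectors[i, ]
}

#' Train CBOW wave embeddings over a symbol corpus
#'
#' Learns a dense vector for every retained alphabet symbol by predicting
#' each symbol from the average of its context symbols' vectors. The
#' forward pass averages the context rows of the V x N input (projection)
#' matrix, multiplies by the N x V output matrix and applies a softmax over
#' the vocabulary; the cross-entropy loss against the target symbol is
#' minimized by stochastic gradient descent, one update per window
#' position, for `epochs` passes over the corpus. The returned wave
#' vectors are the rows of the input matrix.
#'
#' Training is exactly reproducible: parameters are initialized from R's
#' seeded generator (input matrix uniform in `[-0.5/N, 0.5/N]`, output
#' matrix zero), windows are visited in corpus order, and the learning
#' rate decays linearly to `1e-4` of its starting value across all
#' updates. Windows never cross instance boundaries.
#'
#' @param corpus List of [wv_symseq].
#' @param window Window parameter (see [make_training_windows()]);
#'   default 10 context symbols per side.
#' @param dim Embedding dimension N (default 50).
#' @param epochs Number of passes over the corpus (default 3; the
#'   vector-sum classifier downstream converges within the first few
#'   passes).
#' @param learning_rate Initial SGD step size.
#' @param min_frequency Vocabulary filter (see [build_vocab()]).
#' @param seed Integer seed for parameter initialization.
#' @return A [wv_vectable]; attribute `epoch_loss` holds the mean
#'   cross-entropy per epoch.
#' @examples
#' corpus <- list(wv_symseq(c("a", "b", "a", "c"), "s1"))
#' tab <- train_cbow(corpus, window = 3, dim = 4, epochs = 2, seed = 1)
#' dim(tab$vectors)
#' @export
train_cbow <- function(corpus, window = 10L, dim = 50L, epochs = 3L,
                       learning_rate = 0.05, min_frequency = 1L, seed = 1L) {
  stopifnot(is_corpus(corpus))
  dim <- as.integer(dim)
  epochs <- as.integer(epochs)
  if (dim < 1L) stop("dim must be positive", call. = FALSE)
  if (epochs < 1L) stop("epochs must be positive", call. = FALSE)
  if (!is.finite(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be positive", call. = FALSE)
  }
  vocab <- build_vocab(corpus, min_frequency)
  v <- length(vocab$symbols)
  cs <- context_per_side(window)
  # sequences as 1-based vocabulary indices, filtered tokens removed
  idx_corpus <- lapply(corpus, function(s) {
    i <- match(s$tokens, vocab$symbols)
    as.integer(i[!is.na(i)])
  })
  idx_corpus <- idx_corpus[vapply(idx_corpus, length, integer(1)) > 0L]
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  w_in <- matrix(stats::runif(v * dim, -0.5 / dim, 0.5 / dim), nrow = v)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  w_out <- matrix(0, nrow = dim, ncol = v)
  fit <- cbow_train_cpp(idx_corpus, w_in, w_out, cs, epochs, learning_rate, 1e-4)
  vectors <- fit$w_in
  rownames(vectors) <- vocab$symbols
  tab <- wv_vectable(vectors, vocab = vocab,
                     config = list(window = window, dim = dim, epochs = epochs,
                                   learning_rate = learning_rate,
                                   min_frequency = min_frequency, seed = seed))
  attr(tab, "epoch_loss") <- as.numeric(fit$epoch_loss)
  attr(tab, "w_out") <- fit$w_out
  tab
}

#' Single-window CBOW forward pass and analytic gradients
#'
#' Exposed for verification: `cbow_forward` returns the softmax
#' probabilities for one window; `cbow_gradients` additionally returns the
#' analytic cross-entropy gradients with respect to the shared context-row
#' update of the input matrix and the full output matrix.
#'
#' @param w_in V x N input (projection) matrix.
#' @param w_out N x V output matrix.
#' @param context Integer vector of 1-based context row indices.
#' @param target 1-based target index.
#' @return `cbow_forward`: numeric probability vector of length V.
#'   `cbow_gradients`: list with `loss`, `probs`, `grad_context` (the N
#'   gradient applied to each context row), `grad_out` (N x V).
#' @export
cbow_forward <- function(w_in, w_out, context) {
  as.numeric(cbow_forward_cpp(w_in, w_out, as.integer(context)))
}

#' @rdname cbow_forward
#' @export
cbow_gradients <- function(w_in, w_out, context, target) {
  cbow_gradients_cpp(w_in, w_out, as.integer(context), as.integer(target))
}
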