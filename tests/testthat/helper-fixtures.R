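# Shared fixtures and independent oracles, built in code at test time.

# random symbol corpus over a small alphabet
random_corpus <- function(n_seq, len_range = c(2L, 30L),
                          alphabet = c("U00", "U01", "D01"), labels = NULL) {
  lapply(seq_len(n_seq), function(i) {
    len <- sample(len_range[1]:len_range[2], 1L)
    wv_symseq(sample(alphabet, len, replace = TRUE),
              instance_id = paste0("s", i),
              label = if (is.null(labels)) NA_character_ else labels[i])
  })
}

# small labeled dataset of raw signals (no planted structure)
random_dataset <- function(n, n_samples = 16L, classes = c("a", "b")) {
  wv_dataset(lapply(seq_len(n), function(i) {
    wv_signal(rnorm(n_samples), 256, instance_id = paste0("x", i),
              label = classes[(i %% length(classes)) + 1L])
  }), classes = classes)
}

# Independent CBOW loss used as the numerical-differentiation oracle in the
# gradient checks; deliberately written in plain R, separate from the
# training code path.
r_cbow_loss <- function(w_in, w_out, context, target) {
  h <- colMeans(w_in[context, , drop = FALSE])
  u <- as.numeric(h %*% w_out)
  p <- exp(u - max(u))
  p <- p / sum(p)
  -log(p[target])
}

# central-difference gradient of r_cbow_loss w.r.t. every matrix entry
numeric_grads <- function(w_in, w_out, context, target, eps = 1e-6) {
  g_in <- array(0, dim(w_in))
  for (i in seq_len(nrow(w_in))) for (j in seq_len(ncol(w_in))) {
    wp <- w_in; wp[i, j] <- wp[i, j] + eps
    wm <- w_in; wm[i, j] <- wm[i, j] - eps
    g_in[i, j] <- (r_cbow_loss(wp, w_out, context, target) -
                   r_cbow_loss(wm, w_out, context, target)) / (2 * eps)
  }
  g_out <- array(0, dim(w_out))
  for (i in seq_len(nrow(w_out))) for (j in seq_len(ncol(w_out))) {
    wp <- w_out; wp[i, j] <- wp[i, j] + eps
    wm <- w_out; wm[i, j] <- wm[i, j] - eps
    g_out[i, j] <- (r_cbow_loss(w_in, wp, context, target) -
                    r_cbow_loss(w_in, wm, context, target)) / (2 * eps)
  }
  list(g_in = g_in, g_out = g_out)
}

# Brute-force pattern-probability oracle: recounts L and G by direct
# substring enumeration and scores per occurrence (mathematically equal to
# the distinct-pattern formulation, via a different code path).
oracle_class_prob <- function(tokens, corpus_tokens, corpus_labels, cls,
                              max_len) {
  occ_count <- function(toks, pat) {
    n <- length(pat)
    if (length(toks) < n) return(0L)
    sum(vapply(seq_len(length(toks) - n + 1L), function(i) {
      all(toks[i:(i + n - 1L)] == pat)
    }, logical(1)))
  }
  total <- 0
  n_tok <- length(tokens)
  for (len in seq_len(max_len)) {
    if (n_tok < len) break
    # G: all pattern occurrences of this length in the training corpus
    G <- sum(vapply(corpus_tokens, function(t) max(0L, length(t) - len + 1L),
                    integer(1)))
    seen <- character(0)
    for (i in seq_len(n_tok - len + 1L)) {
      pat <- tokens[i:(i + len - 1L)]
      key <- paste(pat, collapse = "\r")
      if (key %in% seen) next  # count each distinct pattern once with O
      seen <- c(seen, key)
      O <- occ_count(tokens, pat)
      L <- sum(vapply(which(corpus_labels == cls), function(k) {
        occ_count(corpus_tokens[[k]], pat)
      }, integer(1)))
      if (G > 0) total <- total + O * len * (L / G)
    }
  }
  total / n_tok
}

# every sequence of the given length over an alphabet
all_sequences <- function(alphabet, len) {
  grid <- do.call(expand.grid, c(rep(list(alphabet), len),
                                 stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}
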