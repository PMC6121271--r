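make_table <- function(symbols, vectors) {
  wv_vectable(matrix(vectors, nrow = length(symbols), byrow = TRUE,
                     dimnames = list(symbols, NULL)))
}

test_that("sequence vectors are order-invariant token sums, OOV skipped", {
  tab <- make_table(c("a", "b"), c(1, 0, 0, 1))
  expect_equal(as.numeric(sequence_vector(wv_symseq(c("a", "b"), "s"), tab)),
               c(1, 1))
  # OOV tokens are skipped silently; fully unknown sequences are degenerate
  v <- sequence_vector(wv_symseq(c("a", "zzz"), "s"), tab)
  expect_equal(as.numeric(v), c(1, 0))
  expect_false(attr(v, "degenerate"))
  vd <- sequence_vector(wv_symseq(c("zzz"), "s"), tab)
  expect_equal(as.numeric(vd), c(0, 0))
  expect_true(attr(vd, "degenerate"))

  set.seed(1)
  tab2 <- make_table(letters[1:5], rnorm(5 * 3))
  for (i in 1:50) {
    toks <- sample(letters[1:5], sample(2:20, 1), replace = TRUE)
    v1 <- sequence_vector(wv_symseq(toks, "s"), tab2)
    v2 <- sequence_vector(wv_symseq(sample(toks), "s"), tab2)
    expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)
  }
})

test_that("class models are vector sums over training sequences", {
  tab <- make_table(c("a", "b"), c(1, 0, 0, 1))
  m <- build_class_model(list(wv_symseq("a", "s1"), wv_symseq("b", "s2")),
                         tab, "c1")
  expect_equal(m$model_vector, c(1, 1))
  expect_equal(m$n_training_sequences, 2)
  single <- build_class_model(list(wv_symseq(c("a", "a"), "s1")), tab, "c1")
  expect_equal(single$model_vector, c(2, 0))
  expect_error(build_class_model(list(), tab, "c1"), "zero sequences")
})

test_that("cosine similarity closed forms and invariances", {
  a <- c(1, 2, -3)
  expect_equal(cosine_similarity(a, a), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0, tolerance = 1e-12)
  expect_equal(cosine_similarity(a, -a), -1, tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), a[1:2]), "zero vector")
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5); k <- runif(1, 0.01, 100)
    expect_equal(cosine_similarity(x, y), cosine_similarity(y, x),
                 tolerance = 1e-12)
    expect_equal(cosine_similarity(k * x, y), cosine_similarity(x, y),
                 tolerance = 1e-12)
  }
})

test_that("classification picks the most similar model, ties to list order", {
  tab <- make_table(c("a", "b"), c(1, 0.1, 0.1, 1))
  mA <- structure(list(label = "A", model_vector = c(1, 0),
                       n_training_sequences = 1), class = "wv_classmodel")
  mN <- structure(list(label = "N", model_vector = c(0, 1),
                       n_training_sequences = 1), class = "wv_classmodel")
  res <- classify(wv_symseq("a", "t"), list(mA, mN), tab)
  expect_equal(res$label, "A")
  expect_named(res$scores, c("A", "N"))

  # exact tie: equidistant vector goes to the first model in the list
  tab_tie <- make_table("t", c(1, 1))
  expect_equal(classify(wv_symseq("t", "x"), list(mA, mN), tab_tie)$label, "A")
  expect_equal(classify(wv_symseq("t", "x"), list(mN, mA), tab_tie)$label, "N")

  expect_error(classify(wv_symseq("zzz", "x"), list(mA, mN), tab),
               "unclassifiable")
  expect_error(classify(wv_symseq("a", "x"), list(mA), tab), "at least 2")
})

test_that("decisions are invariant to model rescaling and sum-vs-mean", {
  set.seed(3)
  for (rep in 1:20) {
    tab <- make_table(letters[1:6], rnorm(6 * 4))
    seqs_a <- random_corpus(4, c(3, 12), letters[1:6])
    seqs_b <- random_corpus(4, c(3, 12), letters[1:6])
    tests <- random_corpus(6, c(3, 12), letters[1:6])
    ms <- list(build_class_model(seqs_a, tab, "A"),
               build_class_model(seqs_b, tab, "B"))
    mm <- list(build_class_model(seqs_a, tab, "A", aggregate = "mean"),
               build_class_model(seqs_b, tab, "B", aggregate = "mean"))
    k <- runif(2, 0.01, 50)
    msc <- lapply(1:2, function(i) {
      m <- ms[[i]]; m$model_vector <- m$model_vector * k[i]; m
    })
    for (s in tests) {
      l0 <- classify(s, ms, tab)$label
      expect_equal(classify(s, mm, tab)$label, l0)
      expect_equal(classify(s, msc, tab)$label, l0)
    }
  }
})

test_that("pattern statistics count n-grams per class with conserved totals", {
  corpus <- list(wv_symseq(c("A", "B", "A"), "s1", label = "c"))
  st <- fit_pattern_stats(corpus, max_pattern_len = 2)
  expect_equal(st$L[["A"]][["c"]], 2)
  expect_equal(unname(st$G["1"]), 3)
  expect_equal(sequence_class_prob(wv_symseq("A", "t"), st, "c"),
               1 * 1 * (2 / 3) / 1)
  # unseen pattern contributes nothing
  expect_equal(sequence_class_prob(wv_symseq("Z", "t"), st, "c"), 0)

  # sum over classes of L equals total occurrences of the pattern
  set.seed(4)
  for (rep in 1:10) {
    labels <- sample(c("x", "y"), 6, replace = TRUE)
    corp <- random_corpus(6, c(2, 10), c("A", "B", "C"), labels = labels)
    st2 <- fit_pattern_stats(corp, max_pattern_len = 3)
    toks <- lapply(corp, `[[`, "tokens")
    for (pat in ls(st2$L)) {
      pat_toks <- strsplit(pat, " ")[[1]]
      n <- length(pat_toks)
      total <- sum(vapply(toks, function(t) {
        if (length(t) < n) return(0L)
        sum(vapply(seq_len(length(t) - n + 1L), function(i) {
          all(t[i:(i + n - 1L)] == pat_toks)
        }, logical(1)))
      }, integer(1)))
      expect_equal(sum(st2$L[[pat]]), total)
    }
  }
})

test_that("sequence scoring matches the brute-force enumeration oracle", {
  corpus <- list(
    wv_symseq(c("A", "B", "A", "C"), "s1", label = "c1"),
    wv_symseq(c("B", "B", "C"), "s2", label = "c1"),
    wv_symseq(c("C", "A", "C", "A"), "s3", label = "c2"),
    wv_symseq(c("A", "A", "B"), "s4", label = "c2")
  )
  st <- fit_pattern_stats(corpus, max_pattern_len = 3)
  corpus_tokens <- lapply(corpus, `[[`, "tokens")
  corpus_labels <- vapply(corpus, `[[`, character(1), "label")
  set.seed(5)
  for (len in 1:4) {
    for (toks in all_sequences(c("A", "B", "C"), len)) {
      for (cls in c("c1", "c2")) {
        expect_equal(
          sequence_class_prob(wv_symseq(toks, "t"), st, cls),
          oracle_class_prob(toks, corpus_tokens, corpus_labels, cls, 3),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("pattern-based classification is argmax with lexical tie-break", {
  corpus <- list(wv_symseq(c("A", "A"), "s1", label = "c1"),
                 wv_symseq(c("B", "B"), "s2", label = "c2"))
  st <- fit_pattern_stats(corpus, max_pattern_len = 2)
  expect_equal(classify_by_patterns(wv_symseq(c("A", "A"), "t"), st), "c1")
  expect_equal(classify_by_patterns(wv_symseq(c("B"), "t"), st), "c2")
  # symmetric corpus: a sequence seen equally in both classes ties to the
  # lexically first class
  sym <- list(wv_symseq(c("A", "B"), "s1", label = "c2"),
              wv_symseq(c("A", "B"), "s2", label = "c1"))
  st_sym <- fit_pattern_stats(sym, max_pattern_len = 2)
  expect_equal(classify_by_patterns(wv_symseq(c("A", "B"), "t"), st_sym), "c1")
  expect_error(classify_by_patterns(wv_symseq("Z", "t"), st), "unclassifiable")
})

test_that("pattern and embedding classifiers mostly agree on planted motifs", {
  cfg <- synth_config(n_per_class = 20, length_samples = 128)
  train <- generate_dataset(cfg, seed = 10)
  test <- generate_dataset(cfg, seed = 11)
  q <- fit_quantizer(dataset_deltas(train), base_n = 16)
  train_corpus <- encode_dataset(train, q)
  test_corpus <- encode_dataset(test, q)
  tab <- train_cbow(train_corpus, window = 5, dim = 16, epochs = 3, seed = 1)
  labels <- dataset_labels(train)
  models <- lapply(sort(unique(labels)), function(cl) {
    build_class_model(train_corpus[labels == cl], tab, cl)
  })
  st <- fit_pattern_stats(train_corpus, max_pattern_len = 2)
  emb <- vapply(test_corpus, function(s) classify(s, models, tab)$label,
                character(1))
  pat <- vapply(test_corpus, function(s) classify_by_patterns(s, st),
                character(1))
  expect_gte(mean(emb == pat), 0.8)
})
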