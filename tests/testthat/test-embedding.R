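test_that("vocabulary counting and frequency filtering", {
  corpus <- list(wv_symseq(c("A", "A", "B"), "s1"))
  expect_length(build_vocab(corpus, 1)$symbols, 2)
  v2 <- build_vocab(corpus, 2)
  expect_equal(v2$symbols, "A")
  expect_error(build_vocab(corpus, 5), "empty vocabulary")
})

test_that("training windows center the target with truncated context", {
  s <- wv_symseq(LETTERS[1:7], "s")  # A..G
  w <- make_training_windows(s, window = 7)
  expect_length(w, 7)
  pos_d <- w[[4]]
  expect_equal(pos_d$target, "D")
  expect_setequal(pos_d$context, c("A", "B", "C", "E", "F", "G"))
  expect_length(pos_d$context, 6)

  # boundary truncation, no padding
  w2 <- make_training_windows(wv_symseq(c("A", "B"), "s"), window = 7)
  expect_equal(w2[[1]], list(context = "B", target = "A"))
  expect_equal(w2[[2]], list(context = "A", target = "B"))

  # an even window parameter is the context size per side
  s30 <- wv_symseq(rep(LETTERS[1:3], 10), "s")
  w3 <- make_training_windows(s30, window = 10)
  expect_length(w3[[15]]$context, 20)

  # one pair per token position
  set.seed(1)
  for (i in 1:100) {
    toks <- sample(LETTERS[1:4], sample(2:40, 1), replace = TRUE)
    expect_length(make_training_windows(wv_symseq(toks, "s"), 7), length(toks))
  }

  # out-of-vocabulary tokens are removed before windowing
  vocab <- build_vocab(list(wv_symseq(c("A", "A", "B", "B"), "s")), 1)
  wf <- make_training_windows(wv_symseq(c("A", "Z", "B"), "s"), 3, vocab)
  expect_equal(lapply(wf, `[[`, "context"), list("B", "A"))
})

test_that("CBOW training is deterministic given seed, corpus and config", {
  set.seed(42)
  corpus <- random_corpus(8, c(5, 20), alphabet = c("U00", "U01", "U02", "D01"))
  t1 <- train_cbow(corpus, window = 3, dim = 8, epochs = 2, seed = 9)
  t2 <- train_cbow(corpus, window = 3, dim = 8, epochs = 2, seed = 9)
  expect_identical(t1$vectors, t2$vectors)
  t3 <- train_cbow(corpus, window = 3, dim = 8, epochs = 2, seed = 10)
  expect_false(identical(t1$vectors, t3$vectors))
})

test_that("analytic CBOW gradients match central differences on a toy model", {
  set.seed(5)
  w_in <- matrix(rnorm(5 * 3, sd = 0.3), nrow = 5)   # V=5, N=3
  w_out <- matrix(rnorm(3 * 5, sd = 0.3), nrow = 3)
  for (case in 1:5) {
    context <- sample(1:5, sample(1:3, 1))
    target <- sample(1:5, 1)
    g <- cbow_gradients(w_in, w_out, context, target)
    num <- numeric_grads(w_in, w_out, context, target)
    # each context row receives the same shared gradient
    for (ci in context) {
      rel <- abs(g$grad_context - num$g_in[ci, ]) /
        pmax(abs(num$g_in[ci, ]), 1e-8)
      expect_lt(max(rel), 1e-4)
    }
    rel_out <- abs(g$grad_out - num$g_out) / pmax(abs(num$g_out), 1e-8)
    expect_lt(max(rel_out), 1e-4)
    expect_equal(g$loss, r_cbow_loss(w_in, w_out, context, target),
                 tolerance = 1e-10)
  }
})

test_that("softmax output is a probability distribution at every forward pass", {
  set.seed(6)
  w_in <- matrix(rnorm(12 * 4), nrow = 12)
  w_out <- matrix(rnorm(4 * 12), nrow = 4)
  for (i in 1:20) {
    p <- cbow_forward(w_in, w_out, sample(1:12, sample(1:6, 1)))
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("mean training loss does not increase over the first epochs", {
  cfg <- synth_config(n_per_class = 6, length_samples = 128)
  ds <- generate_dataset(cfg, seed = 3)
  q <- fit_quantizer(dataset_deltas(ds), base_n = 16)
  corpus <- encode_dataset(ds, q)
  tab <- train_cbow(corpus, window = 3, dim = 10, epochs = 5, seed = 1)
  loss <- attr(tab, "epoch_loss")
  expect_length(loss, 5)
  expect_true(all(diff(loss) <= 1e-6))
})

test_that("tokens sharing contexts embed closer than unrelated tokens", {
  wins <- 0
  for (seed in 1:5) {
    set.seed(seed + 100)
    corpus <- lapply(1:40, function(i) {
      ctx <- sample(c("x", "y", "z"), 2, replace = TRUE)
      tgt <- sample(c("a", "b"), 1)          # a and b share all contexts
      other <- c(sample(c("p", "q"), 1), "c", sample(c("r", "s"), 1))
      wv_symseq(c(ctx[1], tgt, ctx[2], other), paste0("s", i))
    })
    tab <- train_cbow(corpus, window = 3, dim = 10, epochs = 20,
                      learning_rate = 0.1, seed = seed)
    va <- wave_vector(tab, "a"); vb <- wave_vector(tab, "b")
    vc <- wave_vector(tab, "c")
    if (cosine_similarity(va, vb) > cosine_similarity(va, vc)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("the vector table covers exactly the retained vocabulary", {
  corpus <- list(wv_symseq(c("A", "A", "B", "C", "A"), "s1"))
  tab <- train_cbow(corpus, window = 3, dim = 4, epochs = 1,
                    min_frequency = 3, seed = 1)
  expect_equal(rownames(tab$vectors), "A")
  tab2 <- train_cbow(corpus, window = 3, dim = 4, epochs = 1, seed = 1)
  expect_setequal(rownames(tab2$vectors), c("A", "B", "C"))
})
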