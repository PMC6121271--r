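test_that("planted motifs appear exactly in the delta series at zero noise", {
  cfg <- synth_config(n_per_class = 1, length_samples = 64, noise_sd = 1e-12,
                      amplitude_scale = 4)
  set.seed(1)
  sig <- generate_instance(cfg, "alcoholic", "t")
  pos <- attr(sig, "motif_positions")
  d <- diff(sig$samples)
  for (k in seq_len(nrow(pos))) {
    span <- pos$position[k]:(pos$position[k] + 2L)
    expect_equal(d[span], c(4, 4, 4), tolerance = 1e-9)
  }
  # off-motif deltas are (near) zero
  off <- setdiff(seq_along(d), unlist(lapply(pos$position, function(p) p:(p + 2L))))
  expect_lt(max(abs(d[off])), 1e-9)
})

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_per_class = 5, length_samples = 64)
  d1 <- generate_dataset(cfg, seed = 9)
  d2 <- generate_dataset(cfg, seed = 9)
  expect_identical(lapply(d1$instances, `[[`, "samples"),
                   lapply(d2$instances, `[[`, "samples"))
  expect_identical(attr(d1, "truth"), attr(d2, "truth"))
  d3 <- generate_dataset(cfg, seed = 10)
  expect_false(identical(d1$instances[[1]]$samples, d3$instances[[1]]$samples))
})

test_that("background deltas match the configured noise level", {
  cfg <- synth_config(n_per_class = 1, length_samples = 1e5 + 1, noise_sd = 2.5,
                      motifs = list(a = list(), b = list()))
  set.seed(2)
  sig <- generate_instance(cfg, "a", "t")
  expect_lt(abs(sd(diff(sig$samples)) / 2.5 - 1), 0.05)
})

test_that("datasets are balanced with a complete truth manifest", {
  cfg <- synth_config(n_per_class = 100)
  ds <- generate_dataset(cfg, seed = 3)
  expect_length(ds$instances, 200)
  labs <- dataset_labels(ds)
  expect_equal(as.vector(table(labs)[ds$classes]), c(100L, 100L))
  truth <- attr(ds, "truth")
  # every instance has its 2 planted occurrences recorded
  expect_equal(nrow(truth), 200 * 2)
  expect_true(all(truth$length == 3))
  # placements never overlap within an instance
  for (id in unique(truth$instance_id[1:20])) {
    rows <- truth[truth$instance_id == id, ]
    spans <- unlist(lapply(seq_len(nrow(rows)), function(i) {
      rows$position[i]:(rows$position[i] + rows$length[i] - 1L)
    }))
    expect_false(anyDuplicated(spans) > 0)
  }
})

test_that("impossible motif placement raises a placement error", {
  expect_error(
    synth_config(n_per_class = 1, length_samples = 8,
                 motifs = list(a = list(list(profile = rep(1, 9),
                                             occurrences = 1, scale = 1)),
                               b = list())),
    "longer than the instance")
  cfg <- synth_config(n_per_class = 1, length_samples = 10,
                      motifs = list(a = list(list(profile = rep(1, 5),
                                                  occurrences = 3, scale = 1)),
                                    b = list()))
  set.seed(4)
  expect_error(generate_instance(cfg, "a", "t"), "cannot place motifs")
})

test_that("planted motifs encode to their expected symbols at 4 sd amplitude", {
  cfg <- synth_config(n_per_class = 60)
  ds <- generate_dataset(cfg, seed = 5)
  q <- fit_quantizer(dataset_deltas(ds), base_n = 64)
  truth <- attr(ds, "truth")
  ids <- vapply(ds$instances, `[[`, character(1), "instance_id")
  hits <- 0L
  for (r in seq_len(nrow(truth))) {
    sig <- ds$instances[[match(truth$instance_id[r], ids)]]
    expected <- motif_symbols(cfg, truth$class[r], truth$motif[r], q)
    toks <- quantize(delta_encode(sig), q)$tokens
    span <- truth$position[r]:(truth$position[r] + truth$length[r] - 1L)
    if (identical(toks[span], expected)) hits <- hits + 1L
  }
  expect_gte(hits / nrow(truth), 0.9)
})

test_that("zero motif amplitude makes the classes indistinguishable", {
  cfg <- synth_config(n_per_class = 10, amplitude_scale = 0)
  ds <- generate_dataset(cfg, seed = 6)
  # delta distributions of the two classes agree (two-sample KS on pooled deltas)
  labs <- dataset_labels(ds)
  d1 <- unlist(lapply(ds$instances[labs == ds$classes[1]],
                      function(s) diff(s$samples)))
  d2 <- unlist(lapply(ds$instances[labs == ds$classes[2]],
                      function(s) diff(s$samples)))
  expect_gt(suppressWarnings(stats::ks.test(d1, d2)$p.value), 0.01)
})

test_that("written datasets read back identically through the text formats", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_per_class = 3, length_samples = 32)
  ds <- generate_dataset(cfg, seed = 7)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_dataset(dir)
  expect_length(back$instances, 6)
  ids <- vapply(ds$instances, `[[`, character(1), "instance_id")
  back_ids <- vapply(back$instances, `[[`, character(1), "instance_id")
  for (i in seq_along(ids)) {
    j <- match(ids[i], back_ids)
    expect_equal(back$instances[[j]]$samples, ds$instances[[i]]$samples,
                 tolerance = 1e-8)
    expect_equal(back$instances[[j]]$label, ds$instances[[i]]$label)
  }
})
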