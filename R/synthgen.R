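#' Configuration for the two-class synthetic signal generator
#'
#' Emulates the structure the classifier assumes: short single-channel
#' trials (by default 1 s at 256 Hz) whose amplitude-change series is white
#' Gaussian noise with class-specific motifs planted in it. Motifs are
#' defined in delta space — a short profile of amplitude changes added to
#' the noise deltas — so the planted pattern survives delta encoding
#' exactly. With `amplitude_scale = 0` the two classes are
#' distributionally identical.
#'
#' The default motifs are a 3-step rise for the first class and a 3-step
#' drop for the second, each planted twice per instance at amplitude
#' `4 * noise_sd`.
#'
#' @param n_per_class Instances generated per class.
#' @param length_samples Samples per instance (default 256).
#' @param sampling_rate_hz Sampling rate attached to instances.
#' @param noise_sd Standard deviation of the background amplitude-change
#'   noise.
#' @param amplitude_scale Multiplier applied to the default motif profiles
#'   (absolute amplitude-change units; default `4 * noise_sd`).
#' @param motifs Optional full override: named list (one entry per class)
#'   of lists of `list(profile = numeric, occurrences = int, scale =
#'   numeric)`. The planted delta fragment is `profile * scale`.
#' @param classes Class labels used when `motifs` is not given.
#' @return A list of class `wv_synthconfig`.
#' @export
synth_config <- function(n_per_class = 100L, length_samples = 256L,
                         sampling_rate_hz = 256, noise_sd = 1.0,
                         amplitude_scale = 4 * noise_sd,
                         motifs = NULL,
                         classes = c("alcoholic", "control")) {
  if (is.null(motifs)) {
    motifs <- stats::setNames(list(
      list(list(profile = c(1, 1, 1), occurrences = 2L, scale = amplitude_scale)),
      list(list(profile = c(-1, -1, -1), occurrences = 2L, scale = amplitude_scale))
    ), classes)
  }
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  for (cls in names(motifs)) {
    for (m in motifs[[cls]]) {
      if (length(m$profile) >= length_samples) {
        stop("motif profile longer than the instance", call. = FALSE)
      }
    }
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         length_samples = as.integer(length_samples),
         sampling_rate_hz = sampling_rate_hz, noise_sd = noise_sd,
         motifs = motifs, classes = names(motifs)),
    class = "wv_synthconfig"
  )
}

place_motifs <- function(n_slots, lens, max_tries = 1000L) {
  # non-overlapping uniform placement of motif start positions
  for (try in seq_len(max_tries)) {
    starts <- integer(0)
    taken <- logical(n_slots)
    ok <- TRUE
    for (len in lens) {
      cand <- which(!vapply(seq_len(n_slots - len + 1L), function(s) {
        any(taken[s:(s + len - 1L)])
      }, logical(1)))
      if (!length(cand)) { ok <- FALSE; break }
      s <- cand[sample.int(length(cand), 1L)]
      taken[s:(s + len - 1L)] <- TRUE
      starts <- c(starts, s)
    }
    if (ok) return(starts)
  }
  stop("cannot place motifs without overlap: reduce occurrences or motif length",
       call. = FALSE)
}

#' Generate one synthetic signal instance
#'
#' Draws white Gaussian amplitude changes (`sd = noise_sd`), adds the
#' class's motif delta-profiles at uniformly drawn non-overlapping
#' positions, and integrates (cumulative sum from 0) to obtain the signal.
#' Deterministic given the R RNG state.
#'
#' @param cfg A [synth_config()].
#' @param label Class label; must have a motif set in `cfg`.
#' @param instance_id Id for the instance.
#' @return A [wv_signal]; attribute `motif_positions` is a data frame with
#'   columns `motif` (index within the class's motif list) and `position`
#'   (1-based index into the delta series).
#' @export
generate_instance <- function(cfg, label, instance_id = "synth") {
  stopifnot(inherits(cfg, "wv_synthconfig"))
  if (!label %in% names(cfg$motifs)) {
    stop("no motif set for class ", label, call. = FALSE)
  }
  n_deltas <- cfg$length_samples - 1L
  deltas <- stats::rnorm(n_deltas, 0, cfg$noise_sd)
  specs <- cfg$motifs[[label]]
  lens <- as.integer(unlist(lapply(seq_along(specs), function(i) {
    rep(length(specs[[i]]$profile), specs[[i]]$occurrences)
  })))
  which_motif <- as.integer(unlist(lapply(seq_along(specs), function(i) {
    rep(i, specs[[i]]$occurrences)
  })))
  positions <- integer(0)
  if (length(lens)) {
    positions <- place_motifs(n_deltas, lens)
    for (k in seq_along(positions)) {
      m <- specs[[which_motif[k]]]
      span <- positions[k]:(positions[k] + length(m$profile) - 1L)
      deltas[span] <- deltas[span] + m$profile * m$scale
    }
  }
  sig <- wv_signal(cumsum(c(0, deltas)), cfg$sampling_rate_hz,
                   instance_id = instance_id, channel = "SYN",
                   label = label)
  attr(sig, "motif_positions") <- data.frame(motif = which_motif,
                                             position = positions)
  sig
}

#' Generate a labeled two-class synthetic dataset
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A [wv_dataset]; attribute `truth` is the ground-truth manifest,
#'   a data frame with one row per planted motif occurrence
#'   (`instance_id`, `class`, `motif`, `position`, `length`).
#' @export
generate_dataset <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "wv_synthconfig"))
  set.seed(as.integer(seed))
  instances <- list()
  truth <- list()
  for (cls in cfg$classes) {
    for (i in seq_len(cfg$n_per_class)) {
      id <- sprintf("%s_%04d", cls, i)
      sig <- generate_instance(cfg, cls, instance_id = id)
      pos <- attr(sig, "motif_positions")
      if (nrow(pos)) {
        truth[[length(truth) + 1L]] <- data.frame(
          instance_id = id, class = cls, motif = pos$motif,
          position = pos$position,
          length = vapply(pos$motif, function(m) {
            length(cfg$motifs[[cls]][[m]]$profile)
          }, integer(1))
        )
      }
      instances[[length(instances) + 1L]] <- sig
    }
  }
  ds <- wv_dataset(instances, classes = cfg$classes)
  attr(ds, "truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(instance_id = character(0), class = character(0),
               motif = integer(0), position = integer(0), length = integer(0))
  ds
}

#' Expected symbol subsequence of a planted motif
#'
#' The symbols a motif's delta profile encodes to under a fitted
#' quantizer, i.e. what the motif should look like in the encoded corpus
#' when noise does not push it across a bin edge.
#'
#' @param cfg A [synth_config()].
#' @param class Class label.
#' @param motif Index into the class's motif list.
#' @param spec A fitted delta-mode [wv_quantizer].
#' @return Character vector of symbols.
#' @export
motif_symbols <- function(cfg, class, motif, spec) {
  m <- cfg$motifs[[class]][[motif]]
  quantize(m$profile * m$scale, spec)$tokens
}

#' Write a synthetic dataset as signal files plus a labels manifest
#'
#' Emits the same per-instance text files and `labels.tsv` that the signal
#' readers consume, and the ground-truth motif manifest as JSON.
#'
#' @param dataset A dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "wv_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- data.frame(
    instance_id = vapply(dataset$instances, `[[`, character(1), "instance_id"),
    class = dataset_labels(dataset)
  )
  for (s in dataset$instances) {
    write_signal(s, file.path(dir, paste0(s$instance_id, ".txt")))
  }
  write_labels(labels, file.path(dir, "labels.tsv"))
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows")
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory containing `*.txt` signal files and `labels.tsv`.
#' @param sampling_rate_hz Sampling rate to attach.
#' @return A [wv_dataset].
#' @export
read_dataset <- function(dir, sampling_rate_hz = 256) {
  labels <- read_labels(file.path(dir, "labels.tsv"))
  lab_map <- stats::setNames(labels$class, labels$instance_id)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  instances <- lapply(files, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    read_signal(f, sampling_rate_hz = sampling_rate_hz, instance_id = id,
                label = if (id %in% names(lab_map)) lab_map[[id]] else NA_character_)
  })
  wv_dataset(instances)
}
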