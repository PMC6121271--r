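#' Down-sample a signal by integer decimation
#'
#' Keeps every r-th sample starting from the first, where r is the (integer)
#' ratio of the original to the target rate. Non-integer ratios are an
#' error rather than being interpolated.
#'
#' @param signal A [wv_signal].
#' @param target_rate_hz Target sampling rate; must divide the original rate.
#' @return A [wv_signal] at the target rate.
#' @export
downsample <- function(signal, target_rate_hz) {
  stopifnot(inherits(signal, "wv_signal"))
  if (target_rate_hz > signal$sampling_rate_hz) {
    stop("target_rate_hz exceeds the signal's sampling rate", call. = FALSE)
  }
  r <- signal$sampling_rate_hz / target_rate_hz
  if (abs(r - round(r)) > 1e-9) {
    stop(sprintf(paste0("non-integer down-sampling ratio %.4g: choose a target ",
                        "rate that divides %g Hz, or resample externally"),
                 r, signal$sampling_rate_hz), call. = FALSE)
  }
  r <- as.integer(round(r))
  kept <- signal$samples[seq(1L, length(signal$samples), by = r)]
  wv_signal(kept, target_rate_hz, instance_id = signal$instance_id,
            channel = signal$channel, label = signal$label)
}

#' Delta-encode a signal
#'
#' Stores only the amplitude changes between successive samples:
#' `deltas[i] = samples[i+1] - samples[i]`. The delta series of an n-sample
#' signal has n-1 values and telescopes back to `last - first`.
#'
#' @param signal A [wv_signal] with at least 2 samples.
#' @return An object of class `wv_deltas`: list with `deltas`, `source_id`,
#'   `label`.
#' @export
delta_encode <- function(signal) {
  stopifnot(inherits(signal, "wv_signal"))
  n <- length(signal$samples)
  if (n < 2L) stop("delta encoding needs at least 2 samples", call. = FALSE)
  structure(
    list(deltas = diff(signal$samples), source_id = signal$instance_id,
         label = signal$label),
    class = "wv_deltas"
  )
}

symbol_alphabet <- function(base_n) {
  half <- base_n %/% 2L - 1L
  width <- max(2L, nchar(as.character(half)))
  fmt <- function(prefix, k) sprintf(paste0(prefix, "%0", width, "d"), k)
  c(fmt("D", half:1L), fmt("U", 0L), fmt("U", 1L:half))
}

#' Fit a Gaussian quantizer on pooled training deltas
#'
#' Fits a normal distribution to the pooled amplitude-change values and
#' divides its central mass (within `clip_z` standard deviations) into
#' equal-probability bins. Values beyond the clip bounds are treated as
#' noise and absorbed by the outermost bins, and the two near-zero bins
#' (tiny rises and tiny drops) are merged into a single center bin `U00` so
#' that sensor jitter is not learned as signal. The alphabet therefore has
#' `base_n - 1` symbols, ordered `D(base_n/2-1) ... D01, U00, U01 ...
#' U(base_n/2-1)`: D-symbols for falling amplitude, U-symbols for rising.
#'
#' @param deltas A `wv_deltas`, a list of them, or a numeric vector of
#'   pooled amplitude changes.
#' @param base_n Even encoding base number, >= 4. Controls the resolution
#'   of the symbol set.
#' @param clip_z Clip bound in standard deviations (default 2).
#' @return An object of class `wv_quantizer` with fields `base_n`, `mu`,
#'   `sigma`, `clip_z`, `bin_edges` (interior edges on the z scale,
#'   length `alphabet size - 1`), `alphabet`, `mode = "delta"`.
#' @examples
#' q <- fit_quantizer(rnorm(1000), base_n = 16)
#' q$alphabet
#' @export
fit_quantizer <- function(deltas, base_n = 64L, clip_z = 2.0) {
  x <- pool_deltas(deltas)
  base_n <- as.integer(base_n)
  if (base_n < 4L || base_n %% 2L != 0L) {
    stop("base_n must be an even integer >= 4", call. = FALSE)
  }
  if (!is.finite(clip_z) || clip_z <= 0) stop("clip_z must be positive", call. = FALSE)
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate delta distribution: sigma is zero", call. = FALSE)
  }
  alphabet <- symbol_alphabet(base_n)
  m <- length(alphabet)  # base_n - 1 bins
  # equal-probability quantiles of N(0,1) restricted to [-clip_z, clip_z];
  # interior edges only -- outer bins extend to +/-Inf and absorb the tails
  plo <- stats::pnorm(-clip_z)
  phi <- stats::pnorm(clip_z)
  probs <- plo + (seq_len(m - 1L) / m) * (phi - plo)
  edges <- stats::qnorm(probs)
  structure(
    list(base_n = base_n, mu = mu, sigma = sigma, clip_z = clip_z,
         bin_edges = edges, alphabet = alphabet, mode = "delta"),
    class = "wv_quantizer"
  )
}

pool_deltas <- function(deltas) {
  if (inherits(deltas, "wv_deltas")) return(deltas$deltas)
  if (is.numeric(deltas)) return(as.numeric(deltas))
  if (is.list(deltas)) {
    return(unlist(lapply(deltas, function(d) {
      if (inherits(d, "wv_deltas")) d$deltas else as.numeric(d)
    }), use.names = FALSE))
  }
  stop("cannot pool deltas from object of class ", class(deltas)[1], call. = FALSE)
}

#' @export
print.wv_quantizer <- function(x, ...) {
  cat(sprintf("<wv_quantizer> mode=%s base_n=%d alphabet=%d symbols\n",
              x$mode, x$base_n, length(x$alphabet)))
  if (x$mode == "delta") {
    cat(sprintf("  mu=%.4g sigma=%.4g clip_z=%g\n", x$mu, x$sigma, x$clip_z))
  } else {
    cat(sprintf("  range=[%g, %g]\n", x$range[1], x$range[2]))
  }
  invisible(x)
}

#' Quantize a delta series into a symbol sequence
#'
#' Each amplitude change is z-scored by the quantizer's pooled training
#' statistics and mapped to the symbol of its containing bin. Changes
#' beyond +/- `clip_z` standard deviations land in the outermost bins
#' (`U(base_n/2-1)` / `D(base_n/2-1)`); tiny changes of either sign land in
#' the merged center bin `U00`.
#'
#' @param deltas A `wv_deltas` or numeric vector.
#' @param spec A fitted [wv_quantizer] in delta mode.
#' @return A [wv_symseq] of the same length as the delta series.
#' @export
quantize <- function(deltas, spec) {
  stopifnot(inherits(spec, "wv_quantizer"))
  if (spec$mode != "delta") stop("quantize() needs a delta-mode quantizer", call. = FALSE)
  if (inherits(deltas, "wv_deltas")) {
    x <- deltas$deltas
    id <- deltas$source_id
    lab <- deltas$label
  } else {
    x <- as.numeric(deltas)
    id <- "seq"
    lab <- NA_character_
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop("non-finite delta at index ", bad[1], call. = FALSE)
  }
  z <- (x - spec$mu) / spec$sigma
  idx <- findInterval(z, spec$bin_edges) + 1L
  wv_symseq(spec$alphabet[idx], instance_id = id, label = lab)
}

#' Decode a symbol sequence back to representative delta values
#'
#' Each symbol maps to the midpoint of its bin; the outermost (clipped)
#' bins use the midpoint of their clip-truncated interval. Round-tripping
#' an in-range delta through quantize/decode is accurate to at most half
#' the local bin width.
#'
#' @param seq A [wv_symseq] whose tokens all belong to `spec`'s alphabet.
#' @param spec The [wv_quantizer] used for encoding.
#' @return A `wv_deltas` of bin-midpoint values.
#' @export
decode <- function(seq, spec) {
  stopifnot(inherits(seq, "wv_symseq"), inherits(spec, "wv_quantizer"))
  idx <- match(seq$tokens, spec$alphabet)
  if (anyNA(idx)) {
    stop("unknown token: ", seq$tokens[which(is.na(idx))[1]], call. = FALSE)
  }
  mids <- bin_midpoints(spec)
  structure(
    list(deltas = mids[idx], source_id = seq$instance_id, label = seq$label),
    class = "wv_deltas"
  )
}

bin_midpoints <- function(spec) {
  if (spec$mode == "delta") {
    lo <- c(-spec$clip_z, spec$bin_edges)
    hi <- c(spec$bin_edges, spec$clip_z)
    spec$mu + spec$sigma * (lo + hi) / 2
  } else {
    lo <- c(spec$range[1], spec$bin_edges)
    hi <- c(spec$bin_edges, spec$range[2])
    (lo + hi) / 2
  }
}

amplitude_digits <- function(base_n) {
  if (base_n <= 36L) {
    c(as.character(0:9), LETTERS)[seq_len(base_n)]
  } else {
    width <- nchar(as.character(base_n - 1L))
    sprintf(paste0("%0", width, "d"), seq_len(base_n) - 1L)
  }
}

#' Build an equal-width amplitude quantizer
#'
#' The direct-amplitude encoding variant: `base_n` equal-width bins over
#' `[lo, hi]`, labeled with base-`base_n` digit symbols (hexadecimal
#' `'0'..'F'` when `base_n = 16`).
#'
#' @param base_n Number of amplitude levels.
#' @param voltage_range Numeric `c(lo, hi)` with `lo < hi`.
#' @return A [wv_quantizer] with `mode = "amplitude"` and a full `base_n`
#'   symbol alphabet (no center merge in this mode).
#' @export
amplitude_quantizer <- function(base_n = 16L, voltage_range) {
  base_n <- as.integer(base_n)
  if (base_n < 2L) stop("base_n must be >= 2", call. = FALSE)
  lo <- voltage_range[1]; hi <- voltage_range[2]
  if (!is.finite(lo) || !is.finite(hi) || !(lo < hi)) {
    stop("voltage range must satisfy lo < hi", call. = FALSE)
  }
  width <- (hi - lo) / base_n
  structure(
    list(base_n = base_n, mu = NA_real_, sigma = NA_real_, clip_z = NA_real_,
         bin_edges = lo + width * seq_len(base_n - 1L),
         alphabet = amplitude_digits(base_n), mode = "amplitude",
         range = c(lo, hi)),
    class = "wv_quantizer"
  )
}

#' Quantize raw amplitudes over a fixed voltage range
#'
#' Maps each sample to the symbol of its equal-width amplitude bin (see
#' [amplitude_quantizer()]). Out-of-range values clamp to the boundary
#' symbols.
#'
#' @param signal A [wv_signal].
#' @inheritParams amplitude_quantizer
#' @return A [wv_symseq], one symbol per sample.
#' @export
quantize_amplitude <- function(signal, base_n = 16L, voltage_range) {
  stopifnot(inherits(signal, "wv_signal"))
  spec <- amplitude_quantizer(base_n, voltage_range)
  idx <- findInterval(signal$samples, spec$bin_edges) + 1L
  wv_symseq(spec$alphabet[idx], instance_id = signal$instance_id,
            label = signal$label)
}

#' Encode a whole dataset into a symbol corpus
#'
#' Convenience wrapper: optional decimation, delta encoding, quantization
#' of every instance with one shared fitted quantizer.
#'
#' @param dataset A [wv_dataset].
#' @param spec A fitted delta-mode [wv_quantizer].
#' @param target_rate_hz Optional decimation target applied before delta
#'   encoding.
#' @return List of [wv_symseq], one per instance, labels carried over.
#' @export
encode_dataset <- function(dataset, spec, target_rate_hz = NULL) {
  stopifnot(inherits(dataset, "wv_dataset"))
  lapply(dataset$instances, function(s) {
    if (!is.null(target_rate_hz)) s <- downsample(s, target_rate_hz)
    quantize(delta_encode(s), spec)
  })
}

#' Pool the delta series of a dataset's instances
#' @inheritParams encode_dataset
#' @return Numeric vector of all amplitude changes.
#' @export
dataset_deltas <- function(dataset, target_rate_hz = NULL) {
  unlist(lapply(dataset$instances, function(s) {
    if (!is.null(target_rate_hz)) s <- downsample(s, target_rate_hz)
    diff(s$samples)
  }), use.names = FALSE)
}
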