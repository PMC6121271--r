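#' Pairwise symbol similarity matrix of a wave vector table
#'
#' Cosine similarity between every pair of alphabet-symbol wave vectors,
#' ordered from the strongest falling symbols through the center bin to
#' the strongest rising symbols, so the bottom-left of a heat map shows
#' large drops and the top-right large rises. The matrix is symmetric
#' with a unit diagonal.
#'
#' Tables from different models live in different vector spaces, so raw
#' vectors are never compared across tables — only similarity matrices
#' (which are basis-free) may be compared, via [matrix_difference()].
#'
#' @param table A [wv_vectable].
#' @param ordering Symbol ordering for the axes; defaults to the table's
#'   row order. Every requested symbol must be present in the table.
#' @param source Free-text tag recording which model the matrix came from.
#' @return Object of class `wv_simmat`: list with `symbols`, `values`
#'   (square matrix in `[-1, 1]`), `source`.
#' @export
similarity_matrix <- function(table, ordering = NULL, source = "model") {
  stopifnot(inherits(table, "wv_vectable"))
  if (is.null(ordering)) ordering <- rownames(table$vectors)
  missing <- setdiff(ordering, rownames(table$vectors))
  if (length(missing)) {
    stop("symbol missing from vector table: ", missing[1], call. = FALSE)
  }
  m <- table$vectors[ordering, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    stop("undefined similarity: zero vector for symbol ",
         ordering[which(norms == 0)[1]], call. = FALSE)
  }
  mn <- m / norms
  values <- tcrossprod(mn)
  values <- pmin(pmax(values, -1), 1)
  dimnames(values) <- list(ordering, ordering)
  structure(list(symbols = ordering, values = values, source = source),
            class = "wv_simmat")
}

#' @export
print.wv_simmat <- function(x, ...) {
  cat(sprintf("<wv_simmat> %dx%d (%s)\n", nrow(x$values), ncol(x$values),
              x$source))
  invisible(x)
}

#' Difference between two similarity matrices
#'
#' Highlights where two class models disagree about symbol clustering.
#' The default mode is the elementwise absolute difference `|M1 - M2|`
#' (a real-valued "XOR": zero where the models agree, large where they
#' differ); `mode = "xor"` first thresholds each matrix at
#' `binarize_threshold` and takes the logical XOR, giving a 0/1 map.
#'
#' @param m1,m2 Two [similarity_matrix()] objects with identical symbol
#'   ordering.
#' @param mode `"absdiff"` (default) or `"xor"`.
#' @param binarize_threshold Threshold for `"xor"` mode (default 0.5).
#' @return A `wv_simmat` holding the difference map (not itself a
#'   similarity matrix: values in `[0, 2]` for absdiff, `{0, 1}` for
#'   xor).
#' @export
matrix_difference <- function(m1, m2, mode = c("absdiff", "xor"),
                              binarize_threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(m1, "wv_simmat"), inherits(m2, "wv_simmat"))
  if (!identical(m1$symbols, m2$symbols)) {
    stop("symbol orderings differ between the two matrices", call. = FALSE)
  }
  values <- if (mode == "absdiff") {
    abs(m1$values - m2$values)
  } else {
    (m1$values >= binarize_threshold) != (m2$values >= binarize_threshold)
  }
  values <- matrix(as.numeric(values), nrow = nrow(m1$values),
                   dimnames = dimnames(m1$values))
  structure(list(symbols = m1$symbols, values = values,
                 source = sprintf("%s(%s, %s)", mode, m1$source, m2$source)),
            class = "wv_simmat")
}

#' Most class-discriminating symbol pairs
#'
#' Ranks the upper-triangle entries (including the diagonal's exclusion)
#' of a difference map by score; the top pairs are the wavelet-pattern
#' combinations whose clustering differs most between the two class
#' models. Symbols decode back to their amplitude-change meaning through
#' the quantizer's symbol dictionary.
#'
#' @param mdiff A difference map from [matrix_difference()].
#' @param k Number of pairs to return.
#' @param spec Optional [wv_quantizer]; when given, each symbol's bin
#'   midpoint (representative amplitude change) is added.
#' @return Data frame with `symbol_i`, `symbol_j`, `score`, ordered by
#'   decreasing score, ties broken by (row, column) index order; columns
#'   `delta_i`, `delta_j` when `spec` is given. If `k` exceeds the number
#'   of pairs the list is truncated with a warning.
#' @export
top_divergent_pairs <- function(mdiff, k = 10L, spec = NULL) {
  stopifnot(inherits(mdiff, "wv_simmat"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- nrow(mdiff$values)
  ut <- which(upper.tri(mdiff$values), arr.ind = TRUE)
  scores <- mdiff$values[ut]
  # order by score desc, then row, then column, for a deterministic ranking
  ord <- order(-scores, ut[, 1], ut[, 2])
  if (k > length(ord)) {
    warning(sprintf("only %d symbol pairs available; truncating k = %d",
                    length(ord), k), call. = FALSE)
    k <- length(ord)
  }
  sel <- ord[seq_len(k)]
  out <- data.frame(
    symbol_i = mdiff$symbols[ut[sel, 1]],
    symbol_j = mdiff$symbols[ut[sel, 2]],
    score = scores[sel]
  )
  if (!is.null(spec)) {
    mids <- stats::setNames(bin_midpoints(spec), spec$alphabet)
    out$delta_i <- mids[out$symbol_i]
    out$delta_j <- mids[out$symbol_j]
    rownames(out) <- NULL
  }
  out
}

#' Per-class similarity matrices and their difference map
#'
#' The pattern-identification workflow: encode the dataset with one shared
#' quantizer, train a separate CBOW table on each class's sequences, build
#' each class's symbol similarity matrix over the symbols common to both
#' vocabularies (ordered fall-to-rise), and return the matrices together
#' with their difference map. Classification normally uses one shared
#' table; per-class tables are what make class structure visible.
#'
#' @param dataset A labeled [wv_dataset] with exactly 2 classes.
#' @param base_n,clip_z Quantizer parameters.
#' @param mode Difference mode, see [matrix_difference()].
#' @param ... CBOW parameters passed to [train_cbow()].
#' @return List with `matrices` (named per class), `difference`
#'   (`wv_simmat`), `quantizer`.
#' @export
compare_class_models <- function(dataset, base_n = 64L, clip_z = 2.0,
                                 mode = "absdiff", ...) {
  stopifnot(inherits(dataset, "wv_dataset"))
  labels <- dataset_labels(dataset)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly 2 classes required", call. = FALSE)
  spec <- fit_quantizer(dataset_deltas(dataset), base_n = base_n, clip_z = clip_z)
  corpus <- encode_dataset(dataset, spec)
  tables <- lapply(classes, function(cl) {
    train_cbow(corpus[labels == cl], ...)
  })
  names(tables) <- classes
  common <- intersect(spec$alphabet,
                      Reduce(intersect, lapply(tables, function(t) rownames(t$vectors))))
  mats <- lapply(classes, function(cl) {
    similarity_matrix(tables[[cl]], ordering = common, source = cl)
  })
  names(mats) <- classes
  list(matrices = mats,
       difference = matrix_difference(mats[[1]], mats[[2]], mode = mode),
       quantizer = spec)
}

# diverging blue -> white -> red palette, fixed so figures are comparable
heat_palette <- function(n = 101L) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n)
}

draw_heatmap <- function(mat, limits, main = NULL, ...) {
  stopifnot(inherits(mat, "wv_simmat"))
  v <- mat$values
  n <- nrow(v)
  pal <- heat_palette()
  graphics::image(
    x = seq_len(n), y = seq_len(n), z = t(v),
    zlim = limits, col = pal, axes = FALSE, xlab = "", ylab = "",
    main = if (is.null(main)) mat$source else main, useRaster = FALSE, ...
  )
  keep <- unique(round(seq(1, n, length.out = min(n, 16L))))
  graphics::axis(1, at = keep, labels = mat$symbols[keep], las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = keep, labels = mat$symbols[keep], las = 2,
                 cex.axis = 0.6)
  graphics::box()
}

#' Render a similarity or difference matrix as a heat-map file
#'
#' Writes a PNG or SVG (by file extension) with the symbol axes in
#' fall-to-rise order and a blue-to-red diverging scale. Color limits are
#' fixed (`[-1, 1]` for similarity, `[0, 2]` for absolute differences) so
#' figures from different models are directly comparable. Rendering is
#' deterministic: the same matrix and settings produce the same file.
#'
#' @param mat A `wv_simmat`.
#' @param path Output path ending in `.png` or `.svg`.
#' @param limits Color scale limits; defaults to `c(-1, 1)` unless all
#'   values are non-negative, then `c(0, 2)`.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(mat, path, limits = NULL, width = 7, height = 7) {
  stopifnot(inherits(mat, "wv_simmat"))
  if (is.null(limits)) {
    # similarity matrices have a unit diagonal; difference maps are
    # non-negative with a zero diagonal
    is_diff <- min(mat$values) >= 0 && all(abs(diag(mat$values)) < 1e-9)
    limits <- if (is_diff) c(0, 2) else c(-1, 1)
  }
  ext <- tolower(tools::file_ext(path))
  opened <- tryCatch({
    if (ext == "svg") {
      grDevices::svg(path, width = width, height = height)
    } else if (ext == "png") {
      grDevices::png(path, width = width * 100, height = height * 100)
    } else {
      stop("unsupported heat-map format: .", ext, call. = FALSE)
    }
    TRUE
  }, error = function(e) stop("cannot open output path ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 4, 2, 1))
  draw_heatmap(mat, limits = limits)
  invisible(path)
}
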