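#' Column dialect for per-instance signal text files
#'
#' The on-disk layout of signal files is configuration, not a fixed format.
#' The default dialect is one amplitude value per line with `#` comment
#' lines. UCI-style trial files (four whitespace-separated columns:
#' trial, channel, sample index, value) are read with
#' `signal_dialect(value_col = 4, channel_col = 2, index_col = 3,
#' channel = "CP6")`.
#'
#' @param comment Comment-line prefix; lines starting with it are skipped.
#' @param sep Field separator regex; default splits on runs of whitespace.
#' @param value_col 1-based column holding the amplitude value.
#' @param channel_col Optional column holding the channel name.
#' @param index_col Optional column holding the 0- or 1-based sample index;
#'   when present rows are sorted by it.
#' @param channel When `channel_col` is set, keep only rows whose channel
#'   equals this string.
#' @return A list of class `wv_dialect`.
#' @export
signal_dialect <- function(comment = "#", sep = "[[:space:]]+", value_col = 1L,
                           channel_col = NULL, index_col = NULL, channel = NULL) {
  structure(
    list(comment = comment, sep = sep, value_col = as.integer(value_col),
         channel_col = if (is.null(channel_col)) NULL else as.integer(channel_col),
         index_col = if (is.null(index_col)) NULL else as.integer(index_col),
         channel = channel),
    class = "wv_dialect"
  )
}

#' Read one signal instance from a text file
#'
#' Parses a per-instance plain-text signal file under a configurable column
#' dialect. The reader never silently drops rows: every line is either a
#' comment, blank, or a parsed data row, and a malformed row is an error
#' naming its line number.
#'
#' @param path Path to the file.
#' @param sampling_rate_hz Sampling rate to attach to the signal.
#' @param dialect A [signal_dialect()].
#' @param instance_id Instance id; defaults to the file name without
#'   extension.
#' @param label Optional class label to attach.
#' @return A [wv_signal].
#' @export
read_signal <- function(path, sampling_rate_hz = 256,
                        dialect = signal_dialect(),
                        instance_id = NULL, label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(instance_id)) {
    instance_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(trimws(lines), dialect$comment) & nzchar(trimws(lines))
  is_blank <- !nzchar(trimws(lines))
  data_lines <- which(!is_comment & !is_blank)

  values <- numeric(0)
  channels <- character(0)
  indices <- numeric(0)
  for (ln in data_lines) {
    fields <- strsplit(trimws(lines[ln]), dialect$sep)[[1]]
    if (length(fields) < dialect$value_col) {
      stop(sprintf("format error at line %d of %s: expected at least %d fields, got %d",
                   ln, path, dialect$value_col, length(fields)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields[dialect$value_col]))
    if (is.na(v)) {
      stop(sprintf("format error at line %d of %s: non-numeric value '%s'",
                   ln, path, fields[dialect$value_col]), call. = FALSE)
    }
    if (!is.null(dialect$channel_col)) {
      if (length(fields) < dialect$channel_col) {
        stop(sprintf("format error at line %d of %s: missing channel field", ln, path),
             call. = FALSE)
      }
      ch <- fields[dialect$channel_col]
      if (!is.null(dialect$channel) && ch != dialect$channel) next
      channels <- c(channels, ch)
    }
    if (!is.null(dialect$index_col)) {
      idx <- suppressWarnings(as.numeric(fields[dialect$index_col]))
      if (is.na(idx)) {
        stop(sprintf("format error at line %d of %s: non-numeric sample index", ln, path),
             call. = FALSE)
      }
      indices <- c(indices, idx)
    }
    values <- c(values, v)
  }
  if (length(values) == 0L) {
    stop("empty signal: no data rows in ", path, call. = FALSE)
  }
  if (!is.null(dialect$index_col)) {
    values <- values[order(indices)]
  }
  channel <- if (!is.null(dialect$channel)) dialect$channel
             else if (length(channels)) channels[1] else NA_character_
  wv_signal(values, sampling_rate_hz, instance_id = instance_id,
            channel = channel, label = label)
}

#' Write a signal instance as a value-per-line text file
#' @param signal A [wv_signal].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "wv_signal"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# instance %s rate %g", signal$instance_id,
                     signal$sampling_rate_hz), con, sep = "\n")
  writeLines(sprintf("%.10g", signal$samples), con, sep = "\n")
  invisible(path)
}

#' Read or write a labels manifest
#'
#' The manifest is a two-column TSV (`instance_id<TAB>class`) kept separate
#' from the signal files so the signals themselves stay label-free.
#'
#' @param path Manifest path.
#' @return `read_labels` returns a data frame with columns `instance_id`
#'   and `class`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("instance_id", "class"),
                          colClasses = "character", comment.char = "#",
                          quote = "", fileEncoding = "UTF-8")
  df
}

#' @rdname read_labels
#' @param labels Data frame with columns `instance_id`, `class`.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(labels$instance_id, labels$class, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Write a symbol-sequence corpus to a text file
#'
#' One instance per line: the instance id followed by its tokens, all
#' whitespace-separated. `read_symbol_corpus(write_symbol_corpus(x))` is the
#' identity.
#'
#' @param corpus List of [wv_symseq] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_symbol_corpus <- function(corpus, path) {
  stopifnot(is_corpus(corpus))
  for (s in corpus) {
    bad <- grepl("[[:space:]]", c(s$instance_id, s$tokens))
    if (any(bad)) {
      stop("serialization error: token or id contains whitespace in instance ",
           s$instance_id, call. = FALSE)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(corpus, function(s) {
    paste(c(s$instance_id, s$tokens), collapse = " ")
  }, character(1))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_symbol_corpus
#' @param labels Optional labels data frame (as from [read_labels()]) used
#'   to attach class labels to the sequences read back.
#' @return `read_symbol_corpus` returns a list of [wv_symseq].
#' @export
read_symbol_corpus <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lab_map <- NULL
  if (!is.null(labels)) {
    lab_map <- stats::setNames(labels$class, labels$instance_id)
  }
  lapply(lines, function(line) {
    fields <- strsplit(line, "[[:space:]]+")[[1]]
    id <- fields[1]
    lab <- if (!is.null(lab_map) && id %in% names(lab_map)) lab_map[[id]] else NA_character_
    wv_symseq(fields[-1], instance_id = id, label = lab)
  })
}

#' Write or read a wave vector table in word2vec text format
#'
#' Header line `"V N"` (vocabulary size, dimension), then one line per
#' token: the token followed by its N vector components. Round-trips
#' preserve values to within 1e-6 absolute error.
#'
#' @param table A [wv_vectable] (see [train_cbow()]).
#' @param path File path.
#' @return `path` invisibly for the writer; a [wv_vectable] for the reader.
#' @export
write_vector_table <- function(table, path) {
  stopifnot(inherits(table, "wv_vectable"))
  m <- table$vectors
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con, sep = "\n")
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.8g", m[i, ])), collapse = " "),
               con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_vector_table
#' @export
read_vector_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("format error: empty vector-table file", call. = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("format error: header must be 'V N'", call. = FALSE)
  }
  v <- hdr[1]; n <- hdr[2]
  if (length(lines) - 1L != v) {
    stop(sprintf("format error: header declares %d rows, file has %d",
                 v, length(lines) - 1L), call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = v, ncol = n)
  toks <- character(v)
  for (i in seq_len(v)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    if (length(fields) != n + 1L) {
      stop(sprintf("format error at line %d: expected %d values, got %d",
                   i + 1L, n, length(fields) - 1L), call. = FALSE)
    }
    toks[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals)) {
      stop(sprintf("format error at line %d: non-numeric vector component", i + 1L),
           call. = FALSE)
    }
    m[i, ] <- vals
  }
  rownames(m) <- toks
  wv_vectable(m)
}

#' Serialize or restore a fitted quantizer
#'
#' Plain-text key-value format (plus the edge list) so an encoding is
#' bit-reproducible across runs and machines.
#'
#' @param spec A [wv_quantizer] as returned by [fit_quantizer()].
#' @param path File path.
#' @return `path` invisibly for the writer; a [wv_quantizer] for the reader.
#' @export
write_quantizer <- function(spec, path) {
  stopifnot(inherits(spec, "wv_quantizer"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("mode %s", spec$mode),
    sprintf("base_n %d", spec$base_n),
    sprintf("mu %.17g", spec$mu),
    sprintf("sigma %.17g", spec$sigma),
    sprintf("clip_z %.17g", spec$clip_z),
    paste(c("alphabet", spec$alphabet), collapse = " "),
    paste(c("bin_edges", sprintf("%.17g", spec$bin_edges)), collapse = " ")
  ), con, sep = "\n")
  invisible(path)
}

#' @rdname write_quantizer
#' @export
read_quantizer <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  kv <- strsplit(lines, " ")
  names(kv) <- vapply(kv, `[`, character(1), 1)
  get1 <- function(key) {
    if (is.null(kv[[key]])) stop("format error: missing key ", key, call. = FALSE)
    kv[[key]][-1]
  }
  structure(
    list(
      base_n = as.integer(get1("base_n")),
      mu = as.numeric(get1("mu")),
      sigma = as.numeric(get1("sigma")),
      clip_z = as.numeric(get1("clip_z")),
      bin_edges = as.numeric(get1("bin_edges")),
      alphabet = get1("alphabet"),
      mode = get1("mode")
    ),
    class = "wv_quantizer"
  )
}
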