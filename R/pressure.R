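#' Construct a pressure sequence
#'
#' A pressure sequence is one motion trial recorded on a body-pressure mat: an
#' ordered stack of sensor-grid frames plus trial metadata. The grid follows a
#' fixed orientation convention: columns are the lateral axis (x, left = 1)
#' and rows the longitudinal axis (y, front = 1), both 1-based.
#'
#' @param frames A list of numeric matrices (one per time point) or a 3-D
#'   array `[row, col, frame]`. All frames must share dimensions and contain
#'   only finite, non-negative values.
#' @param sample_rate Sampling frequency in Hz (default 50).
#' @param subject,task,side,label Trial metadata. `task` is one of
#'   `"back-and-forth"`, `"side-to-side"`, `"up-and-down"`; `side` is
#'   `"healthy"` or `"affected"`; `label` is one of `NC`, `TLF`, `TR`, `SE`.
#' @return An object of class `pressure_sequence`.
#' @examples
#' seq <- pressure_sequence(list(matrix(1, 4, 4), matrix(2, 4, 4)))
#' n_frames(seq)
#' @export
pressure_sequence <- function(frames, sample_rate = 50,
                              subject = NA_character_, task = NA_character_,
                              side = NA_character_, label = NA_character_) {
  if (is.list(frames)) {
    if (length(frames) == 0) {
      abort("A pressure sequence needs at least one frame.")
    }
    dims <- lapply(frames, dim)
    if (any(vapply(dims, is.null, logical(1)))) {
      abort("Every frame must be a matrix.")
    }
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1) {
      abort("All frames must share the same grid dimensions.")
    }
    arr <- array(unlist(frames, use.names = FALSE),
                 dim = c(dims[[1]], length(frames)))
  } else if (is.array(frames) && length(dim(frames)) == 3) {
    arr <- frames
  } else {
    abort("`frames` must be a list of matrices or a 3-D array.")
  }
  if (dim(arr)[3] < 1) {
    abort("A pressure sequence needs at least one frame.")
  }
  if (anyNA(arr) || any(!is.finite(arr))) {
    abort("Pressure values must be finite.")
  }
  if (any(arr < 0)) {
    abort("Pressure values must be non-negative.")
  }
  structure(
    list(frames = arr, sample_rate = sample_rate,
         meta = list(subject = subject, task = task,
                     side = side, label = label)),
    class = "pressure_sequence"
  )
}

#' @export
print.pressure_sequence <- function(x, ...) {
  d <- dim(x$frames)
  m <- x$meta
  cat(sprintf("<pressure_sequence> %dx%d grid, %d frames @ %g Hz\n",
              d[1], d[2], d[3], x$sample_rate))
  cat(sprintf("  subject: %s  task: %s  side: %s  label: %s\n",
              m$subject, m$task, m$side, m$label))
  invisible(x)
}

#' Number of frames in a pressure sequence
#' @param seq A `pressure_sequence`.
#' @return Integer frame count (the trial duration T in samples).
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "pressure_sequence"))
  dim(seq$frames)[3]
}

#' Extract one frame as a matrix
#' @param seq A `pressure_sequence`.
#' @param t Frame index (1-based).
#' @return The `t`-th sensor grid as a numeric matrix.
#' @export
get_frame <- function(seq, t) {
  stopifnot(inherits(seq, "pressure_sequence"))
  if (t < 1 || t > n_frames(seq)) {
    abort("Frame index out of range.")
  }
  seq$frames[, , t]
}

#' Read a pressure sequence from an ASCII frame file
#'
#' Parses the plain-text dialect used for mat exports: each frame is a block
#' of `n_rows` lines with `n_cols` whitespace- or comma-separated numbers;
#' blocks are separated by one or more blank lines; lines starting with `#`
#' are comments. A JSON side-car (same path with `.json` appended, or given
#' explicitly) supplies metadata when present.
#'
#' @param path Path to the ASCII file (or a character vector of lines via
#'   `text`).
#' @param text Optional character vector of lines, used instead of `path`.
#' @param meta_path Optional path to a JSON metadata side-car. Defaults to
#'   `<path>.json` when that file exists.
#' @param sample_rate Sampling frequency in Hz, used when no side-car
#'   provides one.
#' @return A [pressure_sequence()].
#' @export
read_pressure_ascii <- function(path = NULL, text = NULL, meta_path = NULL,
                                sample_rate = 50) {
  if (is.null(text)) {
    if (is.null(path)) abort("Supply `path` or `text`.")
    text <- readLines(path, warn = FALSE)
    if (is.null(meta_path)) {
      side <- paste0(path, ".json")
      if (file.exists(side)) meta_path <- side
    }
  }
  keep <- !grepl("^\\s*#", text)
  blank <- grepl("^\\s*$", text)
  line_no <- seq_along(text)
  data_lines <- which(keep & !blank)
  if (length(data_lines) == 0) {
    abort("Empty pressure file: no data lines found.")
  }
  # group consecutive data lines into frame blocks
  breaks <- c(TRUE, diff(data_lines) > 1)
  block_id <- cumsum(breaks)
  parse_line <- function(i) {
    vals <- strsplit(trimws(text[i]), "[,[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      abort(sprintf("Parse error at line %d: non-numeric value.", i))
    }
    if (any(num < 0)) {
      abort(sprintf("Parse error at line %d: negative pressure value.", i))
    }
    num
  }
  blocks <- split(data_lines, block_id)
  frames <- lapply(blocks, function(lines) {
    rows <- lapply(lines, parse_line)
    ncols <- lengths(rows)
    if (length(unique(ncols)) > 1) {
      bad <- lines[which(ncols != ncols[1])[1]]
      abort(sprintf(
        "Parse error at line %d: expected %d values, found %d.",
        bad, ncols[1], length(rows[[which(lines == bad)]])))
    }
    do.call(rbind, rows)
  })
  dims <- vapply(frames, dim, integer(2))
  if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1) {
    abort("Frames have inconsistent grid dimensions.")
  }
  meta <- list(subject = NA_character_, task = NA_character_,
               side = NA_character_, label = NA_character_)
  if (!is.null(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    meta[names(meta)] <- lapply(names(meta), function(k) m[[k]] %||% meta[[k]])
    sample_rate <- m$sample_rate %||% sample_rate
  }
  pressure_sequence(frames, sample_rate = sample_rate,
                    subject = meta$subject, task = meta$task,
                    side = meta$side, label = meta$label)
}

#' Write a pressure sequence in the ASCII frame dialect
#'
#' Emits one block of rows per frame, blank-line separated, with values
#' printed at a fixed number of decimal places so that repeated writes are
#' byte-identical and a round-trip reproduces every value at the configured
#' precision.
#'
#' @param seq A [pressure_sequence()].
#' @param path Output file path.
#' @param digits Decimal places for formatting (default 3).
#' @param meta_path Optional path for a JSON metadata side-car; `NULL` (the
#'   default) skips it, `NA` writes `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_pressure_ascii <- function(seq, path, digits = 3, meta_path = NULL) {
  stopifnot(inherits(seq, "pressure_sequence"))
  d <- dim(seq$frames)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# pressure sequence: %d frames of %dx%d at %g Hz",
                     d[3], d[1], d[2], seq$sample_rate), con)
  for (t in seq_len(d[3])) {
    fr <- seq$frames[, , t]
    lines <- apply(fr, 1, function(r) {
      paste(formatC(r, format = "f", digits = digits), collapse = " ")
    })
    writeLines(lines, con)
    if (t < d[3]) writeLines("", con)
  }
  if (!is.null(meta_path)) {
    if (is.na(meta_path)) meta_path <- paste0(path, ".json")
    jsonlite::write_json(
      c(seq$meta, list(sample_rate = seq$sample_rate)),
      meta_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Remove the per-sensor bias offset from a pressure sequence
#'
#' Pressure-mat modules carry a sensor-specific offset; a bias matrix recorded
#' with the seat unloaded is subtracted from every frame. Differences that
#' would go negative are clipped to zero, since pressure cannot be negative.
#'
#' @param seq A [pressure_sequence()].
#' @param bias A numeric matrix of offsets with the same dimensions as the
#'   frames.
#' @return A corrected `pressure_sequence` with unchanged metadata.
#' @export
remove_offset <- function(seq, bias) {
  stopifnot(inherits(seq, "pressure_sequence"))
  d <- dim(seq$frames)
  if (!is.matrix(bias) || !all(dim(bias) == d[1:2])) {
    abort(sprintf("Bias matrix must be %dx%d to match the frames.",
                  d[1], d[2]))
  }
  corrected <- pmax(seq$frames - as.vector(bias), 0)
  out <- seq
  out$frames <- corrected
  out
}
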