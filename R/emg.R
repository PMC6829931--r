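#' Construct a surface-EMG recording
#'
#' One trial of multichannel sEMG: a tibble with one column per muscle
#' channel (defaults to the nine trunk muscles LRA, RRA, LOEA, ROEA, LTES,
#' RTES, LLES, RLES, DT) plus sampling and trial metadata.
#'
#' @param channels A data frame or named list of equal-length numeric
#'   vectors, one per muscle (mV).
#' @param sample_rate Sampling frequency in Hz (default 2000).
#' @param subject,side,label Trial metadata.
#' @return An `emg_recording` object.
#' @export
emg_recording <- function(channels, sample_rate = 2000,
                          subject = NA_character_, side = NA_character_,
                          label = NA_character_) {
  ch <- tibble::as_tibble(channels)
  if (ncol(ch) == 0 || nrow(ch) == 0) {
    abort("An EMG recording needs at least one non-empty channel.")
  }
  if (!all(vapply(ch, is.numeric, logical(1)))) {
    abort("All EMG channels must be numeric.")
  }
  structure(
    list(channels = ch, sample_rate = sample_rate,
         meta = list(subject = subject, side = side, label = label)),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channel(s) x %d samples @ %g Hz\n",
              ncol(x$channels), nrow(x$channels), x$sample_rate))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Read an EMG recording from CSV
#'
#' One column per channel, header row of muscle names; an optional JSON
#' side-car (`<path>.json`) supplies `sample_rate`, `subject`, `side`,
#' `label`.
#'
#' @param path CSV file path.
#' @param sample_rate Fallback sampling rate when no side-car provides one.
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(path, sample_rate = 2000) {
  ch <- utils::read.csv(path, check.names = FALSE)
  meta <- list(subject = NA_character_, side = NA_character_,
               label = NA_character_)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    m <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    meta[names(meta)] <- lapply(names(meta), function(k) {
      m[[k]] %||% meta[[k]]
    })
    sample_rate <- m$sample_rate %||% sample_rate
  }
  emg_recording(ch, sample_rate = sample_rate, subject = meta$subject,
                side = meta$side, label = meta$label)
}

# Factor a transfer-function filter into second-order sections. High-order
# narrow-band IIR filters (the 48-52 Hz notch especially) are numerically
# ill-conditioned in direct form; biquad cascades keep roundoff near machine
# precision.
arma_to_sos <- function(flt) {
  z <- polyroot(rev(as.vector(flt$b)))
  p <- polyroot(rev(as.vector(flt$a)))
  g <- flt$b[1] / flt$a[1]
  pair_up <- function(r) {
    used <- logical(length(r))
    pairs <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      rem <- which(!used)
      j <- rem[which.min(Mod(r[rem] - Conj(r[i])))]
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(r[i], r[j])
    }
    pairs
  }
  zp <- pair_up(z)
  pp <- pair_up(p)
  ord <- order(vapply(pp, function(q) -max(Mod(q)), numeric(1)))
  sos <- lapply(seq_along(pp), function(k) {
    zz <- zp[[ord[k]]]
    qq <- pp[[ord[k]]]
    list(b = Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2])),
         a = Re(c(1, -(qq[1] + qq[2]), qq[1] * qq[2])))
  })
  list(sos = sos, g = g)
}

# 4th-order Butterworth applied forward and backward (zero phase), as a
# biquad cascade with odd-reflection edge padding sized to the band's
# ring-down time. The two-pass cascade doubles the effective order;
# cutoffs are in Hz.
butter_filtfilt <- function(x, cutoff_hz, sample_rate, type) {
  w <- cutoff_hz / (sample_rate / 2)
  flt <- signal::butter(4, w, type = type)
  s <- arma_to_sos(flt)
  bw <- if (length(cutoff_hz) == 2) diff(cutoff_hz) else cutoff_hz
  padlen <- max(50, ceiling(3 * sample_rate / bw))
  n <- length(x)
  p <- min(n - 1, padlen)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  for (sec in s$sos) ext <- signal::filter(sec$b, sec$a, ext)
  ext <- rev(ext)
  for (sec in s$sos) ext <- signal::filter(sec$b, sec$a, ext)
  ext <- rev(ext) * s$g^2
  ext[(p + 1):(p + n)]
}

#' Preprocess an sEMG recording
#'
#' The standard activation-amplitude chain, per channel and in order:
#' baseline correction (mean subtraction), zero-phase 4th-order Butterworth
#' band-pass 20–200 Hz, 4th-order Butterworth band-stop notch around the
#' 50 Hz power frequency (48–52 Hz), full-wave rectification, and amplitude
#' normalization by the channel's trial maximum. Rectification and
#' normalization can be switched off to inspect the linear part of the
#' chain.
#'
#' @param rec An [emg_recording()].
#' @param band Band-pass edges in Hz (default `c(20, 200)`).
#' @param notch Band-stop edges in Hz (default `c(48, 52)`); `NULL` skips
#'   the notch.
#' @param rectify Apply full-wave rectification (default `TRUE`).
#' @param normalize `"max"` (divide by the channel's post-rectification
#'   trial maximum, giving values in \[0, 1\]) or `"none"`. Use `"none"`
#'   when amplitudes are compared across trials or sides.
#' @return The processed `emg_recording`.
#' @export
preprocess_emg <- function(rec, band = c(20, 200), notch = c(48, 52),
                           rectify = TRUE, normalize = c("max", "none")) {
  stopifnot(inherits(rec, "emg_recording"))
  normalize <- match.arg(normalize)
  fs <- rec$sample_rate
  if (fs < 2 * band[2]) {
    abort(sprintf(
      "Sample rate %g Hz is too low for a %g Hz band edge (Nyquist).",
      fs, band[2]))
  }
  if (any(vapply(rec$channels, function(ch) length(ch) == 0, logical(1)))) {
    abort("Empty EMG channel.")
  }
  out <- rec
  out$channels <- tibble::as_tibble(lapply(rec$channels, function(ch) {
    ch <- ch - mean(ch)                           # baseline correction
    ch <- butter_filtfilt(ch, band, fs, "pass")   # 20-200 Hz band-pass
    if (!is.null(notch)) {
      ch <- butter_filtfilt(ch, notch, fs, "stop") # 50 Hz notch
    }
    if (rectify) ch <- abs(ch)                    # full-wave rectification
    if (normalize == "max") {
      mx <- max(ch)
      if (mx > 0) ch <- ch / mx
    }
    ch
  }))
  out
}

#' Root mean square of a signal
#'
#' `sqrt(mean(x^2))` over the whole trial segment — the activation-level
#' summary of a processed sEMG channel.
#'
#' @param x Non-empty numeric vector.
#' @return A single non-negative number.
#' @export
rms <- function(x) {
  if (length(x) == 0) abort("RMS of an empty signal is undefined.")
  sqrt(mean(x^2))
}

#' Per-channel RMS table of a recording
#'
#' @param rec An [emg_recording()] (typically after [preprocess_emg()]).
#' @return A tibble with one row per channel: `subject`, `side`, `label`,
#'   `channel`, `rms`.
#' @export
emg_rms <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  tibble::tibble(
    subject = rec$meta$subject,
    side = rec$meta$side,
    label = rec$meta$label,
    channel = names(rec$channels),
    rms = vapply(rec$channels, rms, numeric(1)))
}

#' Average RMS across subjects
#'
#' Aggregates per-subject RMS values into Ave-RMS cells: the mean and SD per
#' grouping cell (by default channel x movement label x body side), the
#' summary used for healthy-vs-affected side comparisons. Cells with a
#' single subject get SD 0 by convention; empty cells are kept and flagged
#' `missing` rather than erroring.
#'
#' @param rms_tbl A tibble of per-trial or per-subject RMS values with at
#'   least the grouping columns and `rms`.
#' @param by Grouping columns (default `c("channel", "label", "side")`).
#' @return A tibble with the grouping columns plus `ave_rms`, `sd_rms`,
#'   `n_subjects`, `missing`.
#' @export
ave_rms <- function(rms_tbl, by = c("channel", "label", "side")) {
  if (nrow(rms_tbl) == 0) abort("Empty RMS table.")
  out <- rms_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      ave_rms = mean(.data$rms),
      sd_rms = if (dplyr::n() > 1) sd(.data$rms) else 0,
      n_subjects = dplyr::n_distinct(.data$subject),
      .groups = "drop") |>
    tidyr::complete(!!!rlang::syms(by))
  out$missing <- is.na(out$ave_rms)
  out$sd_rms[is.na(out$sd_rms) & !out$missing] <- 0
  out
}
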