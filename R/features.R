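#' Per-frame sum of sensor values
#'
#' The SSV series: for each frame, the sum of all sensor values. SSV tracks
#' the total seat load over the trial and is the normalising denominator of
#' the centre-of-pressure series.
#'
#' @param seq A [pressure_sequence()].
#' @return Numeric vector of length `n_frames(seq)`.
#' @export
ssv_series <- function(seq) {
  stopifnot(inherits(seq, "pressure_sequence"))
  d <- dim(seq$frames)
  colSums(matrix(seq$frames, d[1] * d[2], d[3]))
}

#' Average sensor value of a trial
#'
#' ASV = (sum over frames of SSV(t)) / T, i.e. the mean per-frame total
#' pressure over the whole trial. It reflects the average load amplitude of a
#' reaching movement and is the only one of the five features carrying
#' pressure units.
#'
#' @param seq A [pressure_sequence()].
#' @return A single non-negative number (device units).
#' @export
asv <- function(seq) {
  s <- ssv_series(seq)
  if (length(s) < 1) abort("ASV needs at least one frame.")
  sum(s) / length(s)
}

#' Centre-of-pressure series
#'
#' The pressure-weighted mean sensor coordinate per frame: the lateral COP is
#' the weighted mean column index (x), the longitudinal COP the weighted mean
#' row index (y). Frames with zero total pressure have no defined COP and are
#' flagged invalid rather than erroring.
#'
#' @param seq A [pressure_sequence()].
#' @return A tibble with columns `frame`, `lat_cop`, `lon_cop`, `valid`.
#' @export
cop_series <- function(seq) {
  stopifnot(inherits(seq, "pressure_sequence"))
  d <- dim(seq$frames)
  mat <- matrix(seq$frames, d[1] * d[2], d[3])
  x <- rep(seq_len(d[2]), each = d[1])   # lateral = column index
  y <- rep(seq_len(d[1]), times = d[2])  # longitudinal = row index
  ssv <- colSums(mat)
  valid <- ssv > 0
  lat <- as.vector(crossprod(x, mat)) / ssv
  lon <- as.vector(crossprod(y, mat)) / ssv
  lat[!valid] <- NA_real_
  lon[!valid] <- NA_real_
  tibble::tibble(frame = seq_len(d[3]), lat_cop = lat, lon_cop = lon,
                 valid = valid)
}

#' Left/right and front/back pressure-ratio series
#'
#' Per frame, the ratio of the summed pressure of one half of the grid to the
#' other half. In `semantic` mode the left/right ratio splits along the
#' lateral axis (columns 1..n/2 over columns n/2+1..n) and the front/back
#' ratio along the longitudinal axis (rows 1..n/2 over rows n/2+1..n), so
#' each ratio matches its name. `literal` mode swaps the axes (LR over row
#' halves, FB over column halves), retained for fidelity with sources that
#' index the halves by the other coordinate. Frames whose denominator half
#' sums to zero are flagged invalid.
#'
#' @param seq A [pressure_sequence()].
#' @param axis_mode `"semantic"` (default) or `"literal"`.
#' @return A tibble with columns `frame`, `lr_ratio`, `fb_ratio`, `valid`.
#' @export
ratio_series <- function(seq, axis_mode = c("semantic", "literal")) {
  stopifnot(inherits(seq, "pressure_sequence"))
  axis_mode <- match.arg(axis_mode)
  d <- dim(seq$frames)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    abort("Ratio features need even grid dimensions to split into halves.")
  }
  half_sums <- function(margin) {
    # margin 1: split rows into front/back halves; margin 2: columns into
    # left/right halves. Returns per-frame sums of each half.
    n <- d[margin]
    if (margin == 1) {
      a <- apply(seq$frames[seq_len(n / 2), , , drop = FALSE], 3, sum)
      b <- apply(seq$frames[(n / 2 + 1):n, , , drop = FALSE], 3, sum)
    } else {
      a <- apply(seq$frames[, seq_len(n / 2), , drop = FALSE], 3, sum)
      b <- apply(seq$frames[, (n / 2 + 1):n, , drop = FALSE], 3, sum)
    }
    list(a = a, b = b)
  }
  cols <- half_sums(2)
  rows <- half_sums(1)
  if (axis_mode == "semantic") {
    lr_num <- cols$a; lr_den <- cols$b
    fb_num <- rows$a; fb_den <- rows$b
  } else {
    lr_num <- rows$a; lr_den <- rows$b
    fb_num <- cols$a; fb_den <- cols$b
  }
  valid <- lr_den > 0 & fb_den > 0
  lr <- ifelse(lr_den > 0, lr_num / lr_den, NA_real_)
  fb <- ifelse(fb_den > 0, fb_num / fb_den, NA_real_)
  tibble::tibble(frame = seq_len(d[3]), lr_ratio = lr, fb_ratio = fb,
                 valid = valid)
}

#' Full per-frame feature series of a trial
#'
#' Joins the SSV, COP and ratio series into one tibble, with a combined
#' validity mask (`valid` is `TRUE` when the frame has positive total
#' pressure and both ratio denominators are positive).
#'
#' @inheritParams ratio_series
#' @return A tibble with columns `frame`, `time`, `ssv`, `lat_cop`,
#'   `lon_cop`, `lr_ratio`, `fb_ratio`, `valid`.
#' @export
frame_series <- function(seq, axis_mode = c("semantic", "literal")) {
  axis_mode <- match.arg(axis_mode)
  ssv <- ssv_series(seq)
  cop <- cop_series(seq)
  rat <- ratio_series(seq, axis_mode)
  tibble::tibble(
    frame = cop$frame,
    time = (cop$frame - 1) / seq$sample_rate,
    ssv = ssv,
    lat_cop = cop$lat_cop,
    lon_cop = cop$lon_cop,
    lr_ratio = rat$lr_ratio,
    fb_ratio = rat$fb_ratio,
    valid = cop$valid & rat$valid
  )
}

#' Extract the five-feature vector of a trial
#'
#' Computes ASV over all frames and the sample standard deviations (n - 1
#' denominator) of the lateral COP, longitudinal COP, left/right ratio and
#' front/back ratio over the valid frames only. At least two valid frames are
#' required for the standard deviations to exist.
#'
#' For a whole simulated dataset, `extract_features()` maps over the trials
#' and binds one row per trial.
#'
#' @param x A [pressure_sequence()], a `sim_dataset` from
#'   [simulate_dataset()], or a list of pressure sequences.
#' @param axis_mode Passed to [ratio_series()].
#' @param ... Unused.
#' @return A tibble with one row per trial: `subject`, `task`, `side`,
#'   `label`, then the five feature columns of [feature_names()].
#' @export
extract_features <- function(x, ...) {
  UseMethod("extract_features")
}

#' @rdname extract_features
#' @export
extract_features.pressure_sequence <- function(
    x, axis_mode = c("semantic", "literal"), ...) {
  axis_mode <- match.arg(axis_mode)
  fs <- frame_series(x, axis_mode)
  n_valid <- sum(fs$valid)
  if (n_valid < 2) {
    m <- x$meta
    abort(sprintf(
      "Trial (subject %s, task %s, label %s) has %d valid frame(s); at least 2 are needed for SD features.",
      m$subject, m$task, m$label, n_valid))
  }
  v <- fs[fs$valid, ]
  tibble::tibble(
    subject = x$meta$subject,
    task = x$meta$task,
    side = x$meta$side,
    label = x$meta$label,
    asv = asv(x),
    sd_lat_cop = sd(v$lat_cop),
    sd_lon_cop = sd(v$lon_cop),
    sd_lr_ratio = sd(v$lr_ratio),
    sd_fb_ratio = sd(v$fb_ratio)
  )
}

#' @rdname extract_features
#' @export
extract_features.list <- function(
    x, axis_mode = c("semantic", "literal"), ...) {
  axis_mode <- match.arg(axis_mode)
  purrr::map_dfr(x, extract_features, axis_mode = axis_mode)
}

#' @rdname extract_features
#' @export
extract_features.sim_dataset <- function(
    x, axis_mode = c("semantic", "literal"), ...) {
  axis_mode <- match.arg(axis_mode)
  out <- purrr::map_dfr(x$trials, extract_features, axis_mode = axis_mode)
  out$trial <- x$manifest$trial
  dplyr::relocate(out, "trial")
}
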