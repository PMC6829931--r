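# Shared fixtures: tiny grids and sequences built in code.

# A deterministic 4x4 frame with distinct values.
toy_frame <- function(seed = 1, n = 4) {
  with_toy_seed(seed, matrix(round(runif(n * n, 0, 10), 2), n, n))
}

with_toy_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# A small random sequence on an even grid.
toy_sequence <- function(seed = 1, n = 4, t = 3, ...) {
  frames <- with_toy_seed(seed, {
    lapply(seq_len(t), function(i) matrix(round(runif(n * n, 0, 10), 2), n, n))
  })
  pressure_sequence(frames, ...)
}

# A frame with a single active sensor.
point_frame <- function(row, col, value = 1, n = 32) {
  m <- matrix(0, n, n)
  m[row, col] <- value
  m
}

# Brute-force feature oracle: applies the defining formulas sensor by
# sensor with explicit loops, independently of the vectorised package code.
oracle_frame_series <- function(seq, axis_mode = "semantic") {
  d <- dim(seq$frames)
  nr <- d[1]; nc <- d[2]; T_ <- d[3]
  out <- data.frame(ssv = numeric(T_), lat = numeric(T_), lon = numeric(T_),
                    lr = numeric(T_), fb = numeric(T_), valid = logical(T_))
  for (t in seq_len(T_)) {
    fr <- seq$frames[, , t]
    ssv <- 0; sx <- 0; sy <- 0
    left <- 0; right <- 0; front <- 0; back <- 0
    for (row in seq_len(nr)) {
      for (col in seq_len(nc)) {
        p <- fr[row, col]
        ssv <- ssv + p
        sx <- sx + col * p   # x = lateral = column
        sy <- sy + row * p   # y = longitudinal = row
        if (axis_mode == "semantic") {
          if (col <= nc / 2) left <- left + p else right <- right + p
          if (row <= nr / 2) front <- front + p else back <- back + p
        } else {
          if (row <= nr / 2) left <- left + p else right <- right + p
          if (col <= nc / 2) front <- front + p else back <- back + p
        }
      }
    }
    out$ssv[t] <- ssv
    out$lat[t] <- if (ssv > 0) sx / ssv else NA
    out$lon[t] <- if (ssv > 0) sy / ssv else NA
    out$lr[t] <- if (right > 0) left / right else NA
    out$fb[t] <- if (back > 0) front / back else NA
    out$valid[t] <- ssv > 0 && right > 0 && back > 0
  }
  out
}

# Feature table with clearly separated 4-class Gaussian blobs, grouped by
# subject, for classifier plumbing tests that need no pressure simulation.
blob_features <- function(n_subjects = 4, per_class = 6, sep = 6, sd = 0.5,
                          classes = c("NC", "TLF", "TR", "SE"), seed = 1) {
  centers <- list(c(0, 0), c(sep, 0), c(0, sep), c(sep, sep))[
    seq_along(classes)]
  with_toy_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (ci in seq_along(classes)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("S%d", s),
          label = classes[ci],
          f1 = rnorm(per_class, centers[[ci]][1], sd),
          f2 = rnorm(per_class, centers[[ci]][2], sd))
      }
    }
    tibble::as_tibble(do.call(rbind, rows))
  })
}
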