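#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (0.9795 -> 0.980 at three
#' decimals), the convention used when formatting metric reports. Base
#' `round()` rounds ties to even, which disagrees on exactly those boundary
#' cases.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Pick the feature columns to model: the canonical five when present,
# otherwise every numeric column not used as metadata.
resolve_features <- function(data, features = NULL) {
  if (!is.null(features)) {
    missing <- setdiff(features, names(data))
    if (length(missing) > 0) {
      abort(paste0("Feature column(s) not found: ",
                   paste(missing, collapse = ", ")))
    }
    return(features)
  }
  canonical <- intersect(feature_names(), names(data))
  if (length(canonical) > 0) {
    return(canonical)
  }
  meta <- c("subject", "task", "side", "label", "trial", "fold")
  cand <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
  if (length(cand) == 0) {
    abort("No feature columns found in `data`.")
  }
  cand
}

# Order class levels canonically (NC first, then the named compensation
# patterns) so confusion matrices print in a fixed, comparable order.
canonical_class_order <- function(labels) {
  labels <- unique(as.character(labels))
  known <- intersect(c(CLASSES_4, "C"), labels)
  c(known, sort(setdiff(labels, known)))
}
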