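#' Fit a feature standardizer on training data
#'
#' Learns per-feature mean and standard deviation (sample SD) from the
#' training rows, so features can be normalised to zero mean and unit
#' variance. The same fitted transform is applied to test rows; it is never
#' refitted on them, which keeps cross-validation estimates honest.
#'
#' @param data A data frame of training rows.
#' @param features Feature columns to standardize; defaults to the canonical
#'   five of [feature_names()] when present, otherwise all numeric
#'   non-metadata columns.
#' @return A `standardizer` object; see [standardize()].
#' @export
fit_standardizer <- function(data, features = NULL) {
  features <- resolve_features(data, features)
  if (nrow(data) < 2) abort("Standardizer needs at least 2 rows.")
  mu <- vapply(data[features], mean, numeric(1))
  sigma <- vapply(data[features], sd, numeric(1))
  zero <- sigma == 0 | !is.finite(sigma)
  if (any(zero)) {
    abort(paste0("Zero-variance feature(s): ",
                 paste(features[zero], collapse = ", ")))
  }
  structure(list(features = features, mean = mu, sd = sigma),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std A fitted [fit_standardizer()] object.
#' @param data A data frame containing the standardizer's feature columns.
#' @return `data` with the feature columns replaced by z-scores.
#' @export
standardize <- function(std, data) {
  stopifnot(inherits(std, "standardizer"))
  for (f in std$features) {
    data[[f]] <- (data[[f]] - std$mean[[f]]) / std$sd[[f]]
  }
  data
}

#' @export
print.standardizer <- function(x, ...) {
  cat("<standardizer> on", length(x$features), "feature(s)\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.standardizer <- function(x, ...) {
  tibble::tibble(feature = x$features, mean = unname(x$mean),
                 sd = unname(x$sd))
}
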