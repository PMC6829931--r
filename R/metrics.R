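#' Confusion matrix with a fixed class order
#'
#' Counts (true, predicted) label pairs into a square matrix whose rows are
#' true classes and columns predicted classes. Class order defaults to the
#' canonical posture ordering (NC, TLF, TR, SE, or NC, C for the binary
#' detection task), so matrices from different folds line up.
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Optional character vector fixing the class order; defaults
#'   to the canonical ordering of the labels present.
#' @return A `confusion_matrix`: an integer matrix with dimnames
#'   `truth` x `predicted`.
#' @export
confusion <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have the same length.")
  }
  if (is.null(classes)) {
    classes <- canonical_class_order(c(truth, pred))
  }
  unknown <- setdiff(unique(c(truth, pred)), classes)
  if (length(unknown) > 0) {
    abort(paste0("Unknown label(s): ", paste(unknown, collapse = ", ")))
  }
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' F1-score from precision and recall
#'
#' The harmonic mean `2PR/(P + R)`, vectorised. Returns 0 (the reporting
#' convention for undefined cells) when both precision and recall are 0.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return Numeric vector of F1-scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class: precision = TP/(TP + FP), recall = TP/(TP + FN),
#' F1 = harmonic mean of the two. Macro averages are unweighted means over
#' classes. Cells with a 0/0 denominator are reported as 0 with a warning so
#' that reports stay total.
#'
#' @param cm A [confusion()] matrix.
#' @return A `metrics_report`: list with `per_class` (tibble of class,
#'   precision, recall, f1, support), `macro` (one-row tibble of macro
#'   precision/recall/f1) and `accuracy`. Use [tidy()] / [glance()] to get
#'   the tibbles.
#' @export
precision_recall_f1 <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    if (is.matrix(cm) && nrow(cm) == ncol(cm)) {
      cm <- structure(cm, class = c("confusion_matrix", "matrix", "array"),
                      dimnames = dimnames(cm) %||%
                        rep(list(as.character(seq_len(nrow(cm)))), 2))
    } else {
      abort("`cm` must be a square confusion matrix.")
    }
  }
  if (sum(cm) == 0) abort("Empty confusion matrix.")
  classes <- rownames(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warn(sprintf("%s undefined (0/0) for class(es) %s; reported as 0.",
                   what, paste(classes[bad], collapse = ", ")))
    }
    ifelse(bad, 0, num / den)
  }
  precision <- safe_div(tp, tp + fp, "Precision")
  recall <- safe_div(tp, tp + fn, "Recall")
  f1 <- f1_score(precision, recall)
  per_class <- tibble::tibble(
    class = classes, precision = precision, recall = recall, f1 = f1,
    support = as.integer(unname(rowSums(cm))))
  macro <- tibble::tibble(
    precision = mean(precision), recall = mean(recall), f1 = mean(f1))
  structure(
    list(per_class = per_class, macro = macro,
         accuracy = sum(tp) / sum(cm)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Classification metrics\n")
  pc <- x$per_class
  pc[c("precision", "recall", "f1")] <-
    lapply(pc[c("precision", "recall", "f1")], round_half_up, digits)
  print(pc)
  cat(sprintf("Macro: precision %.3f  recall %.3f  F1 %.3f  |  accuracy %.3f\n",
              x$macro$precision, x$macro$recall, x$macro$f1, x$accuracy))
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    precision_macro = x$macro$precision,
    recall_macro = x$macro$recall,
    f1_macro = x$macro$f1,
    accuracy = x$accuracy)
}

#' Two-sided paired t-test
#'
#' Paired comparison of two equal-length measurement vectors (e.g. F1-scores
#' of two classifiers per subject, or affected- vs healthy-side Ave-RMS per
#' subject-muscle cell). Degenerate inputs with zero-variance differences are
#' flagged instead of erroring: identical vectors give t = 0, p = 1; a
#' constant nonzero difference gives an infinite statistic and p = 0.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same length (paired observations).")
  }
  if (length(a) < 2) abort("Paired t-test needs at least 2 pairs.")
  d <- a - b
  if (sd(d) == 0) {
    md <- mean(d)
    return(tibble::tibble(
      statistic = if (md == 0) 0 else Inf * sign(md),
      df = length(d) - 1,
      p_value = if (md == 0) 1 else 0,
      mean_diff = md,
      degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_diff = unname(tt$estimate),
    degenerate = FALSE)
}

#' Friedman rank test across conditions
#'
#' Nonparametric test for differences across conditions (columns) with
#' subjects as blocks (rows), used e.g. to test whether per-subject F1-scores
#' differ across subjects or conditions.
#'
#' @param values A complete numeric matrix or data frame, subjects in rows
#'   and conditions in columns.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
friedman_test <- function(values) {
  m <- as.matrix(values)
  if (anyNA(m)) abort("Friedman test needs a complete table (no NA cells).")
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("Friedman test needs at least 2 subjects and 2 conditions.")
  }
  if (all(apply(m, 1, function(r) max(r) == min(r)))) {
    # every block fully tied: no rank information, statistic 0 by convention
    return(tibble::tibble(statistic = 0, df = ncol(m) - 1, p_value = 1))
  }
  ft <- stats::friedman.test(m)
  tibble::tibble(
    statistic = unname(ft$statistic),
    df = unname(ft$parameter),
    p_value = ft$p.value)
}
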