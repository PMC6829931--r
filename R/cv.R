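#' Assign subjects to cross-validation folds
#'
#' Subject-grouped folds: the partition is over subjects, never trials, so no
#' individual contributes to both training and testing within a fold. With
#' the 8-subject, 4-fold design each fold holds 2 test subjects and the
#' remaining 6 subjects form the training set.
#'
#' @param subjects Vector of subject identifiers (duplicates collapsed).
#' @param n_folds Number of folds (default 4).
#' @param seed Seed for the random assignment; the same seed reproduces the
#'   same partition.
#' @param allow_unequal Permit fold sizes differing by one when the subject
#'   count is not divisible by `n_folds` (default `FALSE`).
#' @return A tibble with columns `subject`, `fold`.
#' @export
make_subject_folds <- function(subjects, n_folds = 4, seed = NULL,
                               allow_unequal = FALSE) {
  subjects <- unique(subjects)
  n <- length(subjects)
  if (n < n_folds) {
    abort(sprintf("%d subject(s) cannot fill %d folds.", n, n_folds))
  }
  if (n %% n_folds != 0 && !allow_unequal) {
    abort(sprintf(
      "%d subjects are not divisible into %d equal folds (set `allow_unequal = TRUE` for uneven folds).",
      n, n_folds))
  }
  shuffled <- with_seed(seed, sample(subjects))
  # contiguous blocks over the shuffled order
  fold <- sort(rep(seq_len(n_folds), length.out = n))
  tibble::tibble(subject = shuffled, fold = fold)
}

#' Collapse the four posture classes to a binary detection task
#'
#' Maps the three compensation patterns (TLF, TR, SE) to a single positive
#' class `"C"`, keeping `"NC"`, which turns the four-class categorisation
#' problem into compensation detection.
#'
#' @param data A data frame with a `label` column.
#' @param positive Name for the pooled compensation class (default `"C"`).
#' @return `data` with the `label` column collapsed to `NC` / `positive`.
#' @export
to_binary_labels <- function(data, positive = "C") {
  data$label <- ifelse(data$label == "NC", "NC", positive)
  data
}

#' Subject-grouped cross-validation of a posture classifier
#'
#' Runs the full evaluation protocol: within each fold, a standardizer is
#' fitted on the training subjects' rows only and applied to both training
#' and test rows; the classifier is trained (for k-NN, k is selected by inner
#' subject-grouped validation when a grid is given) and evaluated on the
#' held-out subjects. Per-fold confusion matrices and metrics are returned
#' together with a pooled (micro-aggregated) confusion matrix across folds.
#'
#' @param data Feature table: columns `subject`, `label`, and the feature
#'   columns.
#' @param classifier `"knn"` or `"svm"`.
#' @param folds A [make_subject_folds()] tibble; by default built from the
#'   data's subjects with `n_folds` and `seed`.
#' @param n_folds,seed Used when `folds` is `NULL`.
#' @param k Fixed neighbour count for k-NN; `NULL` (default) selects k from
#'   `k_grid` per fold.
#' @param k_grid Candidate k values for [select_k()].
#' @param C Soft-margin cost for the SVM.
#' @param scheme Multiclass scheme for the SVM.
#' @param features,label_col Column selection.
#' @return A `cv_result` object; see [tidy()] and [glance()] methods.
#' @export
cross_validate <- function(data, classifier = c("knn", "svm"), folds = NULL,
                           n_folds = 4, seed = NULL, k = NULL,
                           k_grid = seq(1, 15, by = 2), C = 1,
                           scheme = "ovr", features = NULL,
                           label_col = "label") {
  classifier <- match.arg(classifier)
  features <- resolve_features(data, features)
  if (is.null(folds)) {
    folds <- make_subject_folds(data$subject, n_folds = n_folds, seed = seed)
  }
  missing_subj <- setdiff(unique(data$subject), folds$subject)
  if (length(missing_subj) > 0) {
    abort(paste0("Subjects without a fold: ",
                 paste(missing_subj, collapse = ", ")))
  }
  classes <- canonical_class_order(data[[label_col]])
  fold_ids <- sort(unique(folds$fold))

  fold_out <- purrr::map(fold_ids, function(f) {
    test_subj <- folds$subject[folds$fold == f]
    tr <- data[!data$subject %in% test_subj, , drop = FALSE]
    te <- data[data$subject %in% test_subj, , drop = FALSE]
    if (nrow(te) == 0) abort(sprintf("Fold %d has no test rows.", f))
    if (length(unique(tr[[label_col]])) < length(classes)) {
      abort(sprintf("Training set of fold %d lacks a class.", f))
    }
    std <- fit_standardizer(tr, features)
    tr_z <- standardize(std, tr)
    te_z <- standardize(std, te)
    if (classifier == "knn") {
      k_used <- k %||% select_k(tr, candidates = k_grid, features = features,
                                label_col = label_col,
                                seed = (seed %||% 0) + f)
      model <- fit_knn(tr_z, k = k_used, features = features,
                       label_col = label_col)
    } else {
      k_used <- NA_integer_
      model <- fit_svm(tr_z, C = C, features = features,
                       label_col = label_col, scheme = scheme)
    }
    pred <- predict(model, te_z)
    cm <- confusion(te[[label_col]], pred, classes = classes)
    list(fold = f, k = k_used, test_subjects = test_subj, cm = cm,
         predictions = tibble::tibble(
           fold = f, subject = te$subject,
           truth = as.character(te[[label_col]]), pred = pred))
  })

  pooled <- Reduce(`+`, lapply(fold_out, `[[`, "cm"))
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix", "array"),
                      dimnames = list(truth = classes, predicted = classes))
  structure(
    list(classifier = classifier, classes = classes, folds = folds,
         fold_results = fold_out, pooled_cm = pooled,
         predictions = purrr::map_dfr(fold_out, "predictions"),
         params = list(k = k, k_grid = k_grid, C = C, scheme = scheme,
                       features = features, seed = seed)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_result> %s, %d folds, %d test trials, classes: %s\n",
    x$classifier, length(x$fold_results), sum(x$pooled_cm),
    paste(x$classes, collapse = ", ")))
  cat(sprintf(
    "  pooled: accuracy %.3f  macro F1 %.3f  (fold-mean macro F1 %.3f)\n",
    g$accuracy, g$f1_macro, g$f1_macro_foldmean))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  purrr::map_dfr(x$fold_results, function(fr) {
    rep <- suppressWarnings(precision_recall_f1(fr$cm))
    out <- rep$per_class
    out$fold <- fr$fold
    out$k <- fr$k
    dplyr::relocate(out, "fold")
  })
}

#' @export
glance.cv_result <- function(x, ...) {
  pooled <- suppressWarnings(precision_recall_f1(x$pooled_cm))
  fold_macro <- vapply(x$fold_results, function(fr) {
    suppressWarnings(precision_recall_f1(fr$cm))$macro$f1
  }, numeric(1))
  tibble::tibble(
    classifier = x$classifier,
    accuracy = pooled$accuracy,
    precision_macro = pooled$macro$precision,
    recall_macro = pooled$macro$recall,
    f1_macro = pooled$macro$f1,
    f1_macro_foldmean = mean(fold_macro),
    n_folds = length(x$fold_results),
    n_test = sum(x$pooled_cm))
}

#' Per-class metrics of the pooled cross-validation confusion matrix
#'
#' @param x A `cv_result`.
#' @return A [precision_recall_f1()] report on the fold-pooled confusion
#'   matrix.
#' @export
cv_metrics <- function(x) {
  stopifnot(inherits(x, "cv_result"))
  precision_recall_f1(x$pooled_cm)
}
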