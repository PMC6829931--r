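#' Run the full detection pipeline end-to-end
#'
#' Generates (or accepts) a labeled dataset, extracts the five-feature table
#' and evaluates both classifiers under subject-grouped cross-validation on
#' the two tasks the method targets: per-reaching-task binary compensation
#' detection (NC vs C) and four-class categorisation of the compensation
#' pattern (NC/TLF/TR/SE) over all trials.
#'
#' @param params A [sim_params()] object (ignored when `features` is
#'   given).
#' @param features Optional precomputed feature table (columns `subject`,
#'   `task`, `label` + features); when `NULL` a dataset is simulated from
#'   `params`.
#' @param classifiers Classifiers to evaluate (default both).
#' @param n_folds Number of subject-grouped folds (default 4).
#' @param seed Root seed: the dataset uses `seed`, the fold assignment
#'   `seed + 1`.
#' @param axis_mode Passed to [extract_features()].
#' @param k_grid,C Hyperparameters for [cross_validate()].
#' @return A `pipeline_result`: list with `features`, `folds`, `summary` (a
#'   tibble with one row per classifier x task: the binary positive-class F1
#'   per reaching task, the NC-positive F1, and the 4-class macro F1), and
#'   `cv` (the underlying `cv_result` objects).
#' @export
run_pipeline <- function(params = sim_params(), features = NULL,
                         classifiers = c("knn", "svm"), n_folds = 4,
                         seed = 1, axis_mode = "semantic",
                         k_grid = seq(1, 15, by = 2), C = 1) {
  if (is.null(features)) {
    dataset <- simulate_dataset(params, seed = seed)
    features <- extract_features(dataset, axis_mode = axis_mode)
  }
  folds <- make_subject_folds(unique(features$subject), n_folds = n_folds,
                              seed = seed + 1)
  cv_objects <- list()
  rows <- list()
  for (clf in classifiers) {
    # four-class categorisation over all trials
    cv4 <- cross_validate(features, classifier = clf, folds = folds,
                          k_grid = k_grid, C = C, seed = seed)
    cv_objects[[paste0(clf, "_4class")]] <- cv4
    g4 <- glance(cv4)
    rows[[length(rows) + 1]] <- tibble::tibble(
      classifier = clf, task = "4-class", positive = NA_character_,
      f1 = g4$f1_macro, accuracy = g4$accuracy,
      f1_macro_foldmean = g4$f1_macro_foldmean)
    # per-task binary detection, compensation as the positive class
    for (tk in unique(features$task)) {
      sub <- to_binary_labels(features[features$task == tk, , drop = FALSE])
      cvb <- cross_validate(sub, classifier = clf, folds = folds,
                            k_grid = k_grid, C = C, seed = seed)
      cv_objects[[paste0(clf, "_binary_", tk)]] <- cvb
      per_class <- suppressWarnings(cv_metrics(cvb))$per_class
      gb <- glance(cvb)
      rows[[length(rows) + 1]] <- tibble::tibble(
        classifier = clf, task = tk, positive = "C",
        f1 = per_class$f1[per_class$class == "C"],
        f1_nc_positive = per_class$f1[per_class$class == "NC"],
        accuracy = gb$accuracy,
        f1_macro_foldmean = gb$f1_macro_foldmean)
    }
  }
  structure(
    list(features = features, folds = folds,
         summary = dplyr::bind_rows(rows), cv = cv_objects,
         seed = seed),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d trials, %d subjects, seed %s\n",
              nrow(x$features), length(unique(x$features$subject)),
              format(x$seed)))
  s <- x$summary
  s$f1 <- round_half_up(s$f1, 3)
  s$accuracy <- round_half_up(s$accuracy, 3)
  print(s[c("classifier", "task", "f1", "accuracy")], n = Inf)
  invisible(x)
}

#' Write the feature table and evaluation reports of a pipeline run
#'
#' Persists the artifacts of [run_pipeline()]: the feature table and the
#' summary as CSV, the fold assignment and a manifest (seed, parameters
#' digest) as JSON, and each pooled confusion matrix as a labeled CSV.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @param digits Display rounding for the summary CSV; the JSON manifest
#'   keeps full precision.
#' @return Invisibly, `dir`.
#' @export
write_pipeline_reports <- function(result, dir, digits = 3) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  summary_out <- result$summary
  num <- vapply(summary_out, is.numeric, logical(1))
  summary_out[num] <- lapply(summary_out[num], round_half_up, digits)
  utils::write.csv(summary_out, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = result$seed, folds = result$folds,
         summary = result$summary),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (nm in names(result$cv)) {
    cm <- result$cv[[nm]]$pooled_cm
    utils::write.csv(as.data.frame(unclass(cm)),
                     file.path(dir, paste0("confusion_", nm, ".csv")))
  }
  invisible(dir)
}
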