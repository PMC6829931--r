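#' Euclidean distance between two feature vectors
#'
#' `sqrt(sum((x - y)^2))`, the metric used by the k-NN classifier.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) abort("Vectors must have equal length.")
  sqrt(sum((x - y)^2))
}

# All pairwise Euclidean distances between rows of `a` (queries) and `b`
# (training points); returns a length(a-rows) x length(b-rows) matrix.
cross_distances <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit a k-nearest-neighbour classifier
#'
#' Stores the (already standardized) training vectors and labels; prediction
#' takes the majority label among the k nearest training rows by Euclidean
#' distance. Ties are broken deterministically: among vote-tied classes the
#' class of the best-ranked (nearest) neighbour wins, and neighbours at equal
#' distance are ordered by training-row index.
#'
#' @param data Training data frame with a label column and feature columns.
#' @param k Odd positive neighbour count; must not exceed the number of
#'   training rows.
#' @param features,label_col Column selection (see [fit_standardizer()]).
#' @return A `seatcomp_knn` model with a [predict()] method.
#' @export
fit_knn <- function(data, k = 3, features = NULL, label_col = "label") {
  features <- resolve_features(data, features)
  labels <- as.character(data[[label_col]])
  if (length(unique(labels)) < 2) {
    abort("k-NN training needs at least 2 classes.")
  }
  if (k > nrow(data)) {
    abort(sprintf("k = %d exceeds the training size (%d).", k, nrow(data)))
  }
  if (k < 1) abort("k must be a positive count.")
  structure(
    list(k = as.integer(k), features = features,
         x = as.matrix(data[features]), y = labels,
         classes = canonical_class_order(labels)),
    class = "seatcomp_knn")
}

#' @export
print.seatcomp_knn <- function(x, ...) {
  cat(sprintf("<k-NN classifier> k = %d, %d training rows, classes: %s\n",
              x$k, nrow(x$x), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @rdname fit_knn
#' @param object A fitted `seatcomp_knn` model.
#' @param newdata Data frame of query rows with the model's feature columns.
#' @param ... Unused.
#' @export
predict.seatcomp_knn <- function(object, newdata, ...) {
  q <- as.matrix(newdata[object$features])
  dmat <- cross_distances(q, object$x)
  apply(dmat, 1, function(d) {
    # stable order: by distance, then by training-row index
    ord <- order(d, seq_along(d))[seq_len(object$k)]
    votes <- table(object$y[ord])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1) return(winners)
    # tie: the winner containing the best-ranked neighbour
    for (idx in ord) {
      if (object$y[idx] %in% winners) return(object$y[idx])
    }
  })
}

#' Choose k by inner subject-grouped validation
#'
#' Runs the candidate neighbour counts through a subject-grouped inner
#' cross-validation on the training set and returns the k with the highest
#' macro F1; ties go to the smallest k, so the simplest model wins.
#'
#' @param data Training rows, including a `subject` column.
#' @param candidates Odd k values to try (default 1, 3, ..., 15).
#' @param n_inner Number of inner folds (default 3, capped at the number of
#'   training subjects).
#' @param seed Seed for the inner fold assignment.
#' @inheritParams fit_knn
#' @return The selected k (integer).
#' @export
select_k <- function(data, candidates = seq(1, 15, by = 2), n_inner = 3,
                     features = NULL, label_col = "label", seed = 1) {
  features <- resolve_features(data, features)
  subjects <- unique(data$subject)
  if (length(subjects) < 2) {
    abort("k selection needs at least 2 training subjects.")
  }
  if (length(candidates) == 1) return(as.integer(candidates))
  n_inner <- min(n_inner, length(subjects))
  folds <- make_subject_folds(subjects, n_folds = n_inner, seed = seed,
                              allow_unequal = TRUE)
  min_train <- min(vapply(seq_len(n_inner), function(f) {
    sum(data$subject %in% folds$subject[folds$fold != f])
  }, numeric(1)))
  candidates <- sort(candidates[candidates <= min_train])
  if (length(candidates) == 0) {
    abort("No candidate k fits the inner training size.")
  }
  score <- vapply(candidates, function(k) {
    f1s <- vapply(seq_len(n_inner), function(f) {
      test_subj <- folds$subject[folds$fold == f]
      tr <- data[!data$subject %in% test_subj, ]
      te <- data[data$subject %in% test_subj, ]
      std <- fit_standardizer(tr, features)
      model <- fit_knn(standardize(std, tr), k = k, features = features,
                       label_col = label_col)
      pred <- predict(model, standardize(std, te))
      cm <- confusion(te[[label_col]], pred, classes = model$classes)
      suppressWarnings(precision_recall_f1(cm)$macro$f1)
    }, numeric(1))
    mean(f1s)
  }, numeric(1))
  as.integer(candidates[which.max(score)])  # which.max takes the first tie
}

#' Fit a linear soft-margin support-vector machine
#'
#' Linear SVM on standardized features, one binary machine per class in a
#' one-vs-rest scheme (one-vs-one available). Each binary machine maximises
#' the margin subject to soft-margin constraints; its hyperplane is stored
#' explicitly as a weight vector `w` and bias `b` so the decision function is
#' `f(x) = w'x + b` with `f > 0` for the machine's positive class. The
#' quadratic program is solved by libsvm (via e1071); on separable data with
#' large cost the margin constraints `y_i (w'x_i + b) >= 1` hold at
#' convergence tolerance.
#'
#' @param data Training data frame (standardized features).
#' @param C Soft-margin cost (default 1).
#' @param scheme Multiclass decomposition: `"ovr"` (one-vs-rest, default) or
#'   `"ovo"` (one-vs-one voting).
#' @param tolerance Termination tolerance of the quadratic-program solver
#'   (default 1e-6, tight enough that the margin constraints hold to 1e-6 on
#'   separable data).
#' @inheritParams fit_knn
#' @return A `seatcomp_svm` model: per-machine `w`, `b`, support-vector
#'   indices, and a [predict()] method.
#' @export
fit_svm <- function(data, C = 1, features = NULL, label_col = "label",
                    scheme = c("ovr", "ovo"), tolerance = 1e-6) {
  scheme <- match.arg(scheme)
  features <- resolve_features(data, features)
  labels <- as.character(data[[label_col]])
  classes <- canonical_class_order(labels)
  if (length(classes) < 2) abort("SVM training needs at least 2 classes.")
  x <- as.matrix(data[features])

  fit_binary <- function(pos_mask, name) {
    yf <- factor(ifelse(pos_mask, "pos", "neg"), levels = c("pos", "neg"))
    if (length(unique(yf)) < 2) {
      abort(sprintf("Binary machine %s has a single class.", name))
    }
    m <- e1071::svm(x = x, y = yf, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = tolerance)
    w <- as.vector(t(m$coefs) %*% m$SV)
    b <- -m$rho
    # align sign so that f(x) > 0 predicts the positive class
    f <- as.vector(x %*% w + b)
    pred_pos <- predict(m, x) == "pos"
    agree <- mean((f > 0) == pred_pos)
    if (agree < 0.5) {
      w <- -w
      b <- -b
    }
    list(name = name, w = w, b = b, sv_index = m$index)
  }

  if (scheme == "ovr" || length(classes) == 2) {
    machines <- lapply(classes, function(cl) fit_binary(labels == cl, cl))
    names(machines) <- classes
    pairs <- NULL
  } else {
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    machines <- lapply(pairs, function(p) {
      keep <- labels %in% p
      sub <- x[keep, , drop = FALSE]
      yf <- factor(ifelse(labels[keep] == p[1], "pos", "neg"),
                   levels = c("pos", "neg"))
      m <- e1071::svm(x = sub, y = yf, kernel = "linear", cost = C,
                      scale = FALSE, tolerance = tolerance)
      w <- as.vector(t(m$coefs) %*% m$SV)
      b <- -m$rho
      f <- as.vector(sub %*% w + b)
      if (mean((f > 0) == (predict(m, sub) == "pos")) < 0.5) {
        w <- -w
        b <- -b
      }
      list(name = paste(p, collapse = "/"), pair = p, w = w, b = b,
           sv_index = which(keep)[m$index])
    })
  }
  structure(
    list(features = features, classes = classes, scheme =
           if (length(classes) == 2) "ovr" else scheme,
         C = C, machines = machines, pairs = pairs),
    class = "seatcomp_svm")
}

#' @export
print.seatcomp_svm <- function(x, ...) {
  cat(sprintf("<linear SVM> %s over classes %s, C = %g, %d machine(s)\n",
              x$scheme, paste(x$classes, collapse = ", "), x$C,
              length(x$machines)))
  invisible(x)
}

#' @rdname fit_svm
#' @param object A fitted `seatcomp_svm` model.
#' @param newdata Data frame of query rows (standardized like the training
#'   rows).
#' @param ... Unused.
#' @export
predict.seatcomp_svm <- function(object, newdata, ...) {
  q <- as.matrix(newdata[object$features])
  if (object$scheme == "ovr") {
    scores <- vapply(object$machines, function(m) {
      as.vector(q %*% m$w + m$b)
    }, numeric(nrow(q)))
    scores <- matrix(scores, nrow = nrow(q))
    object$classes[apply(scores, 1, which.max)]
  } else {
    votes <- matrix(0, nrow(q), length(object$classes),
                    dimnames = list(NULL, object$classes))
    for (m in object$machines) {
      f <- as.vector(q %*% m$w + m$b)
      winner <- ifelse(f > 0, m$pair[1], m$pair[2])
      for (cl in object$classes) {
        votes[, cl] <- votes[, cl] + (winner == cl)
      }
    }
    object$classes[apply(votes, 1, which.max)]
  }
}

#' @export
tidy.seatcomp_svm <- function(x, ...) {
  purrr::map_dfr(x$machines, function(m) {
    tibble::tibble(machine = m$name, term = c(x$features, "(bias)"),
                   estimate = c(m$w, m$b))
  })
}
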