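test_that("standardizer centres and scales, and is learned from training only", {
  # features {1, 3}: mean 2, sample SD sqrt(2) -> z = -1/sqrt(2), +1/sqrt(2)
  d <- tibble::tibble(f = c(1, 3))
  std <- fit_standardizer(d, "f")
  expect_equal(standardize(std, d)$f, c(-1, 1) / sqrt(2))

  # random table: transformed moments are 0/1, verified by recomputation
  set.seed(5)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(250, 5, 3), 50, 5)))
  std <- fit_standardizer(tab, names(tab))
  z <- standardize(std, tab)
  expect_equal(unname(colMeans(as.matrix(z))), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(as.matrix(z), 2, sd)), rep(1, 5),
               tolerance = 1e-9)

  # idempotent on already-standardized data
  std2 <- fit_standardizer(z, names(tab))
  expect_equal(as.matrix(standardize(std2, z)), as.matrix(z),
               tolerance = 1e-9)

  tab$flat <- 1
  expect_error(fit_standardizer(tab, c("V1", "flat")), "flat")
})

test_that("Euclidean distance and k-NN match the exhaustive-sort oracle", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)

  # k = 1 nearest point wins
  train <- tibble::tibble(f = c(0, 10), label = c("A", "B"))
  m1 <- fit_knn(train, k = 1, features = "f")
  expect_equal(predict(m1, tibble::tibble(f = 1)), "A")

  # k = 3 on random 2-D configurations agrees with brute force
  set.seed(17)
  for (rep in 1:5) {
    tr <- tibble::tibble(f1 = rnorm(12), f2 = rnorm(12),
                         label = rep(c("A", "B", "C"), 4))
    qu <- tibble::tibble(f1 = rnorm(6), f2 = rnorm(6))
    model <- fit_knn(tr, k = 3, features = c("f1", "f2"))
    got <- predict(model, qu)
    want <- vapply(seq_len(nrow(qu)), function(i) {
      d <- sqrt((tr$f1 - qu$f1[i])^2 + (tr$f2 - qu$f2[i])^2)
      nb <- tr$label[order(d)][1:3]
      tal <- table(nb)
      winners <- names(tal)[tal == max(tal)]
      if (length(winners) == 1) winners else nb[nb %in% winners][1]
    }, character(1))
    expect_equal(got, want)
  }

  # k = 1 reproduces the training labels on distinct training points
  expect_equal(predict(fit_knn(tr, k = 1), tr), tr$label)
})

test_that("k-NN tie-breaking is deterministic and favours the nearest", {
  # two votes each at k = 4: class of the nearest neighbour wins
  tr <- tibble::tibble(f = c(1, 2, -1.5, -2.5), label = c("A", "A", "B", "B"))
  m <- fit_knn(tr, k = 4, features = "f")
  expect_equal(predict(m, tibble::tibble(f = 0)), "A")  # nearest is f = 1

  # equal distances: lowest training-row index breaks the order
  tr2 <- tibble::tibble(f = c(1, -1), label = c("A", "B"))
  m2 <- fit_knn(tr2, k = 2, features = "f")
  expect_equal(predict(m2, tibble::tibble(f = 0)), "A")

  expect_error(fit_knn(tr2, k = 5), "exceeds")
})

test_that("k selection sweeps candidates and prefers the smallest tie", {
  feats <- blob_features(n_subjects = 4, per_class = 5, sep = 8, sd = 0.4)
  # single candidate passes through
  expect_equal(select_k(feats, candidates = 3), 3L)
  # perfectly separated classes: every k works, smallest returned
  expect_equal(select_k(feats, candidates = c(1, 3, 5)), 1L)

  # noisy set: matches an exhaustive per-candidate evaluation
  noisy <- blob_features(n_subjects = 4, per_class = 6, sep = 2, sd = 1.2,
                         seed = 9)
  cands <- c(1, 3, 5, 7)
  got <- select_k(noisy, candidates = cands, seed = 4)
  scores <- vapply(cands, function(k) {
    folds <- make_subject_folds(unique(noisy$subject), 3, seed = 4,
                                allow_unequal = TRUE)
    mean(vapply(1:3, function(f) {
      te_s <- folds$subject[folds$fold == f]
      tr <- noisy[!noisy$subject %in% te_s, ]
      te <- noisy[noisy$subject %in% te_s, ]
      std <- fit_standardizer(tr, c("f1", "f2"))
      mod <- fit_knn(standardize(std, tr), k = k, features = c("f1", "f2"))
      cm <- confusion(te$label, predict(mod, standardize(std, te)),
                      classes = canonical_class_order(noisy$label))
      suppressWarnings(precision_recall_f1(cm))$macro$f1
    }, numeric(1)))
  }, numeric(1))
  expect_equal(got, as.integer(cands[which.max(scores)]))
})

test_that("linear SVM solves the hard-margin toy analytically", {
  # 1-D points -1 (class A), +1 (class B), huge cost: boundary at 0
  d <- tibble::tibble(f = c(-1, 1), label = c("A", "B"))
  m <- fit_svm(d, C = 1e6, features = "f")
  mac <- m$machines[["B"]]
  expect_equal(unname(mac$w), 1, tolerance = 1e-4)
  expect_equal(mac$b, 0, tolerance = 1e-4)
  expect_equal(predict(m, tibble::tibble(f = c(-0.2, 0.2))), c("A", "B"))
})

test_that("SVM satisfies margin constraints on separable data", {
  set.seed(23)
  feats <- blob_features(n_subjects = 2, per_class = 10, sep = 6, sd = 0.5,
                         classes = c("NC", "TLF", "TR"))
  std <- fit_standardizer(feats, c("f1", "f2"))
  z <- standardize(std, feats)
  m <- fit_svm(z, C = 1e4, features = c("f1", "f2"))

  # zero training error
  expect_equal(predict(m, z), z$label)

  # every binary machine: y_i (w'x_i + b) >= 1 - 1e-6 at large cost
  x <- as.matrix(z[c("f1", "f2")])
  for (cl in names(m$machines)) {
    mac <- m$machines[[cl]]
    y <- ifelse(z$label == cl, 1, -1)
    margins <- y * (x %*% mac$w + mac$b)
    expect_true(all(margins >= 1 - 1e-6))
  }

  # duplicating the training set leaves predictions unchanged
  dup <- dplyr::bind_rows(z, z)
  m2 <- fit_svm(dup, C = 1e4, features = c("f1", "f2"))
  expect_equal(predict(m2, z), predict(m, z))

  single <- z[z$label == "NC", ]
  expect_error(fit_svm(single, features = c("f1", "f2")), "class")
})

test_that("subject folds partition subjects reproducibly", {
  subj <- sprintf("S%d", 1:8)
  f <- make_subject_folds(subj, n_folds = 4, seed = 3)
  expect_equal(sort(f$subject), subj)           # union = all subjects
  expect_equal(as.vector(table(f$fold)), rep(2L, 4))  # two per fold
  expect_equal(anyDuplicated(f$subject), 0L)    # pairwise disjoint

  expect_equal(make_subject_folds(subj, 4, seed = 3), f)  # determinism
  expect_error(make_subject_folds(subj[1:7], 4), "divisible")
  expect_equal(nrow(make_subject_folds(subj[1:7], 4, allow_unequal = TRUE)),
               7)
})

test_that("cross-validation isolates test subjects and hits chance for a trivial rule", {
  feats <- blob_features(n_subjects = 4, per_class = 6, sep = 6, sd = 0.5)

  # well-separated blobs: both classifiers essentially perfect
  for (clf in c("knn", "svm")) {
    cv <- cross_validate(feats, clf, n_folds = 4, seed = 8, k = 3)
    expect_gte(glance(cv)$f1_macro, 0.95)
  }

  # leak detector: perturbing one test subject's rows leaves the training
  # standardizer of that fold unchanged
  cv <- cross_validate(feats, "knn", n_folds = 4, seed = 8, k = 3)
  folds <- cv$folds
  target <- folds$subject[folds$fold == 1][1]
  shifted <- feats
  shifted[shifted$subject == target, c("f1", "f2")] <-
    shifted[shifted$subject == target, c("f1", "f2")] + 100
  tr_ref <- fit_standardizer(feats[feats$subject != target &
                                     !feats$subject %in%
                                     folds$subject[folds$fold == 1], ],
                             c("f1", "f2"))
  tr_shift <- fit_standardizer(shifted[shifted$subject != target &
                                         !shifted$subject %in%
                                         folds$subject[folds$fold == 1], ],
                               c("f1", "f2"))
  expect_equal(tidy(tr_ref), tidy(tr_shift))
  # and the shifted test subject's own predictions are the only ones that
  # may change
  cv_shift <- cross_validate(shifted, "knn", folds = folds, k = 3)
  keep <- cv$predictions$subject != target
  expect_equal(cv_shift$predictions$pred[keep], cv$predictions$pred[keep])

  # every trial is tested exactly once
  expect_equal(nrow(cv$predictions), nrow(feats))
  expect_equal(sum(cv$pooled_cm), nrow(feats))

  # a constant majority-class rule on a balanced 4-class set scores ~ 0.25
  cm <- confusion(feats$label, rep("NC", nrow(feats)),
                  classes = c("NC", "TLF", "TR", "SE"))
  expect_equal(suppressWarnings(precision_recall_f1(cm))$accuracy, 0.25)

  # rescaling all features before standardization changes nothing
  scaled <- feats
  scaled[c("f1", "f2")] <- scaled[c("f1", "f2")] * 40
  cv_scaled <- cross_validate(scaled, "knn", folds = folds, k = 3)
  expect_equal(cv_scaled$predictions$pred, cv$predictions$pred)
})

test_that("binary collapse maps compensation patterns to one positive class", {
  d <- tibble::tibble(label = c("NC", "TLF", "TR", "SE"))
  expect_equal(to_binary_labels(d)$label, c("NC", "C", "C", "C"))
})
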