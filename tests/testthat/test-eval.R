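# Splits, folds, classifier roster, metric suite, experiment harness.

test_that("holdout split is stratified, disjoint and exhaustive", {
  labels <- factor(rep(rhythm_classes(), each = 25))
  sp <- make_holdout_split(labels, 0.5, seed = 1L)
  expect_length(sp$train, 52)  # 13 per class with round-half-away
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  tab_tr <- table(labels[sp$train])
  tab_te <- table(labels[sp$test])
  expect_true(all(abs(tab_tr - tab_te) <= 1))
  expect_identical(sp, make_holdout_split(labels, 0.5, seed = 1L))
  expect_error(make_holdout_split(factor(c("a", "b", "b"))),
               "stratification error")
})

test_that("holdout partition properties hold for random label vectors", {
  set.seed(5)
  for (i in 1:8) {
    labels <- factor(sample(letters[1:3], 60, replace = TRUE,
                            prob = c(0.5, 0.3, 0.2)))
    frac <- runif(1, 0.3, 0.7)
    sp <- make_holdout_split(labels, frac, seed = i)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_along(labels))
    expect_true(all(table(labels[sp$train]) >= 1))
    expect_true(all(table(labels[sp$test]) >= 1))
  }
})

test_that("cv folds are stratified partitions covering each sample once", {
  labels <- factor(rep(rhythm_classes(), each = 10))
  folds <- make_cv_folds(labels, k = 10, seed = 3L)
  expect_length(folds, 10)
  test_sets <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(test_sets) == 4))
  expect_setequal(unlist(test_sets), seq_along(labels))
  expect_equal(sum(lengths(test_sets)), length(labels))  # pairwise disjoint
  global <- table(labels) / length(labels)
  for (f in folds) {
    cnt <- table(labels[f$test])
    expect_true(all(abs(cnt - global * length(f$test)) <= 1))
    expect_setequal(c(f$train, f$test), seq_along(labels))
  }
  expect_error(make_cv_folds(factor(c("a", "b")), k = 10), "config error")
  expect_warning(make_cv_folds(factor(rep(c("a", "b"), c(30, 4))), k = 10),
                 "stratification is partial")
})

test_that("classifiers separate two distant Gaussian blobs perfectly", {
  set.seed(17)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 8), ncol = 2))
  y <- factor(rep(c("lo", "hi"), each = 30))
  for (nm in classifier_names()) {
    pred <- train_and_predict(x, y, x, nm, seed = 4L)
    expect_equal(mean(pred == y), 1, info = nm)
  }
})

test_that("1-NN memorises its training set", {
  set.seed(23)
  x <- matrix(rnorm(80), ncol = 4)
  y <- factor(sample(rhythm_classes(), 20, replace = TRUE))
  pred <- train_and_predict(x, y, x, "fine_knn")
  expect_equal(as.character(pred), as.character(y))
})

test_that("cubic SVM separates an XOR arrangement at training time", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
  y <- factor(c("a", "a", "b", "b"))
  pred <- train_and_predict(x, y, x, "cubic_svm")
  expect_equal(as.character(pred), as.character(y))
})

test_that("degenerate classifier inputs are contract errors", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(train_and_predict(x, factor(rep("a", 10)), x, "linear_svm"),
               "single class")
  expect_error(train_and_predict(x, factor(rep(c("a", "b"), 5)),
                                 matrix(rnorm(9), ncol = 3), "linear_svm"),
               "shape error")
})

test_that("metrics from a diagonal confusion matrix are perfect", {
  cm <- confusion_matrix(factor(rep(rhythm_classes(), each = 5)),
                         factor(rep(rhythm_classes(), each = 5)))
  rep <- compute_metrics(cm)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_equal(rep$fnr, 0)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$f_score, 1)
})

test_that("metrics match hand counts on a binary confusion matrix", {
  m <- matrix(c(50, 50, 0, 100), nrow = 2, byrow = TRUE,
              dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- compute_metrics(structure(m, class = "confusion_matrix"))
  expect_equal(rep$accuracy, 75)  # (50 + 100) / 200
  expect_equal(rep$per_class$sensitivity[1], 50)  # 50 / (50 + 50)
  expect_equal(rep$per_class$specificity[1], 100)  # no false positives for pos
  expect_equal(rep$per_class$fnr[1], 50)
})

test_that("sensitivity + FNR is exactly 100 on random confusion matrices", {
  set.seed(71)
  for (i in 1:15) {
    c_n <- sample(2:5, 1)
    m <- matrix(rpois(c_n * c_n, 20), c_n, c_n)
    m[cbind(1:c_n, 1:c_n)] <- m[cbind(1:c_n, 1:c_n)] + 5  # non-empty rows
    rep <- compute_metrics(structure(m, class = "confusion_matrix"))
    expect_equal(rep$sensitivity + rep$fnr, 100)
    expect_equal(rep$per_class$sensitivity + rep$per_class$fnr, rep(100, c_n))
    expect_true(all(rep$per_class$sensitivity >= 0 &
                      rep$per_class$sensitivity <= 100))
    expect_true(rep$f_score >= 0 && rep$f_score <= 1)
  }
})

test_that("a class with no true samples yields recall zero with a warning", {
  m <- matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(rep <- compute_metrics(structure(m, class = "confusion_matrix")),
                 "no true samples")
  expect_equal(rep$per_class$sensitivity[1], 0)
})

test_that("experiments report per roster entry and respect selection", {
  set.seed(101)
  n <- 60
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  x <- matrix(rnorm(n * 12), ncol = 12)
  x[, 1] <- x[, 1] + 3 * as.integer(y)  # informative feature
  roster <- list("fine_knn", "linear_svm", "linear_discriminant")
  reports <- run_experiment(x, y, roster = roster, protocol = "cv10", seed = 2L)
  expect_length(reports, 3)
  expect_equal(vapply(reports, function(r) r$classifier$name, character(1)),
               unlist(roster))
  # pooled CV confusion matrix covers every sample exactly once
  expect_equal(sum(reports[[1]]$confusion), n)
  # selecting all features equals no selection
  sel_all <- select_by_entropy(x, fraction = 1)
  r_none <- run_experiment(x, y, roster = list("fine_knn"), seed = 2L)
  r_all <- run_experiment(x, y, roster = list("fine_knn"),
                          selection = sel_all, seed = 2L)
  expect_equal(r_none[[1]]$confusion[, ], r_all[[1]]$confusion[, ])
  # holdout protocol scores the held-out half only
  r_h <- run_experiment(x, y, roster = list("fine_knn"),
                        protocol = "holdout5050", seed = 2L)
  expect_equal(sum(r_h[[1]]$confusion), n / 2)
  # reproducibility under the same seed
  r_rep <- run_experiment(x, y, roster = list("fine_knn"), seed = 2L)
  expect_identical(r_none[[1]]$confusion, r_rep[[1]]$confusion)
})

test_that("the feature-count sweep reports one accuracy per count", {
  set.seed(33)
  y <- factor(rep(c("a", "b"), each = 20))
  x <- matrix(rnorm(40 * 10), ncol = 10)
  x[, 3] <- x[, 3] + 4 * (y == "b")
  sweep_tab <- selection_sweep(x, y, counts = c(2, 5, 10),
                               spec = classifier_spec("fine_knn"),
                               protocol = "cv10", k = 5, seed = 1L)
  expect_equal(sweep_tab$n_features, c(2L, 5L, 10L))
  expect_true(all(sweep_tab$accuracy >= 0 & sweep_tab$accuracy <= 100))
  expect_error(selection_sweep(x, y, counts = 99), "counts")
})
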