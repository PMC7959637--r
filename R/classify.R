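# Classifier roster. The named configurations reconstruct the MATLAB
# Classification Learner presets the result tables cite; every parameter is
# overridable through classifier_spec(). SVMs and discriminants see
# z-scored features (statistics from the training half only); KNN variants
# operate on raw features.

#' Names of the supported classifiers
#'
#' @return Character vector of roster names.
#' @export
classifier_names <- function() {
  c("linear_svm", "quadratic_svm", "cubic_svm", "linear_discriminant",
    "fine_knn", "medium_knn", "cubic_knn", "weighted_knn",
    "subspace_discriminant", "subspace_knn")
}

#' Describe a classifier configuration
#'
#' Default hyperparameters per name: linear/quadratic/cubic SVM use a
#' polynomial kernel of degree 1/2/3 with `coef0 = 1`, box constraint
#' (cost) 1 and one-vs-one multiclass; fine/medium KNN are Euclidean with
#' k = 1 / k = 10; cubic KNN is Minkowski p = 3 with k = 10; weighted KNN is
#' k = 10 with inverse-squared-distance weights; the subspace ensembles draw
#' 30 random feature subspaces of dimension `ceiling(D/2)` with a linear
#' discriminant or 1-NN base learner and majority-vote.
#'
#' @param name One of [classifier_names()].
#' @param ... Hyperparameter overrides (`cost`, `degree`, `k`, `p`,
#'   `weighted`, `n_learners`, `subspace_dim`).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name, ...) {
  name <- match.arg(name, classifier_names())
  defaults <- switch(name,
    linear_svm    = list(kind = "svm", degree = 1L, cost = 1),
    quadratic_svm = list(kind = "svm", degree = 2L, cost = 1),
    cubic_svm     = list(kind = "svm", degree = 3L, cost = 1),
    linear_discriminant = list(kind = "lda"),
    fine_knn      = list(kind = "knn", k = 1L, p = 2, weighted = FALSE),
    medium_knn    = list(kind = "knn", k = 10L, p = 2, weighted = FALSE),
    cubic_knn     = list(kind = "knn", k = 10L, p = 3, weighted = FALSE),
    weighted_knn  = list(kind = "knn", k = 10L, p = 2, weighted = TRUE),
    subspace_discriminant = list(kind = "subspace", base = "lda",
                                 n_learners = 30L, subspace_dim = NULL),
    subspace_knn  = list(kind = "subspace", base = "knn1",
                         n_learners = 30L, subspace_dim = NULL)
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyperparameters = hp), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf("classifier_spec %s (%s): %s\n", x$name, hp$kind,
              paste(sprintf("%s=%s", names(hp)[-1],
                            vapply(hp[-1], function(v)
                              paste(format(v), collapse = ","), character(1))),
                    collapse = " ")))
  invisible(x)
}

# z-score columns using training statistics; sd 0 columns divide by 1.
#' @noRd
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

#' @noRd
standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu, "-"), 2, st$sd, "/")
}

# Minkowski-distance KNN with optional inverse-squared-distance weights.
# Vote ties break toward the earliest class level (deterministic).
#' @noRd
knn_predict <- function(train_x, train_y, test_x, k, p = 2, weighted = FALSE) {
  train_y <- as.factor(train_y)
  k <- min(k, nrow(train_x))
  n_test <- nrow(test_x)
  lev <- levels(train_y)
  pred <- character(n_test)
  # distances computed per test chunk to bound memory
  chunk <- max(1L, floor(2e6 / nrow(train_x)))
  for (start in seq(1, n_test, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_test)
    if (p == 2) {
      d2 <- outer(rowSums(test_x[rows, , drop = FALSE]^2),
                  rowSums(train_x^2), "+") -
        2 * tcrossprod(test_x[rows, , drop = FALSE], train_x)
      d <- sqrt(pmax(d2, 0))
    } else {
      d <- t(apply(test_x[rows, , drop = FALSE], 1, function(q) {
        (colSums(abs(t(train_x) - q)^p))^(1 / p)
      }))
      if (length(rows) == 1) d <- matrix(d, nrow = 1)
    }
    for (i in seq_along(rows)) {
      ord <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
      if (weighted) {
        w <- 1 / pmax(d[i, ord], 1e-12)^2
      } else {
        w <- rep(1, k)
      }
      votes <- vapply(lev, function(cl) sum(w[train_y[ord] == cl]), numeric(1))
      pred[i] <- lev[which.max(votes)]
    }
  }
  factor(pred, levels = lev)
}

#' @noRd
lda_predict <- function(train_x, train_y, test_x) {
  keep <- apply(train_x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stopf("all training features constant; discriminant undefined")
  fit <- suppressWarnings(MASS::lda(train_x[, keep, drop = FALSE],
                                    grouping = train_y))
  stats::predict(fit, test_x[, keep, drop = FALSE])$class
}

#' Train a classifier and predict test labels
#'
#' Fits the configuration described by `spec` on the training data and
#' returns predictions for the test rows. SVM and discriminant classifiers
#' see features z-scored with training-set statistics; KNN variants use raw
#' features. Results are deterministic given `seed` (randomness enters only
#' through the subspace ensembles' feature draws).
#'
#' @param train_x,train_y Training feature matrix and labels (>= 2 classes).
#' @param test_x Test feature matrix with the same columns as `train_x`.
#' @param spec A [classifier_spec()] (or a roster name, converted with
#'   defaults).
#' @param seed Integer seed for the ensemble subspace draws.
#'
#' @return Factor of predicted labels, levels as in `train_y`.
#' @export
train_and_predict <- function(train_x, train_y, test_x, spec, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) {
    stopf("shape error: train has %d columns, test has %d",
          ncol(train_x), ncol(test_x))
  }
  train_y <- droplevels(as.factor(train_y))
  if (nlevels(train_y) < 2) {
    stopf("contract error: training data has a single class")
  }
  hp <- spec$hyperparameters
  switch(hp$kind,
    svm = {
      st <- standardize_fit(train_x)
      xs <- standardize_apply(train_x, st)
      ts <- standardize_apply(test_x, st)
      fit <- e1071::svm(xs, train_y, kernel = "polynomial",
                        degree = hp$degree, coef0 = 1, cost = hp$cost,
                        scale = FALSE)
      stats::predict(fit, ts)
    },
    lda = {
      st <- standardize_fit(train_x)
      lda_predict(standardize_apply(train_x, st),
                  train_y, standardize_apply(test_x, st))
    },
    knn = knn_predict(train_x, train_y, test_x,
                      k = hp$k, p = hp$p, weighted = hp$weighted),
    subspace = {
      st <- standardize_fit(train_x)
      xs <- if (hp$base == "lda") standardize_apply(train_x, st) else train_x
      ts <- if (hp$base == "lda") standardize_apply(test_x, st) else test_x
      d <- ncol(train_x)
      sdim <- hp$subspace_dim
      if (is.null(sdim)) sdim <- ceiling(d / 2)
      sdim <- min(sdim, d)
      lev <- levels(train_y)
      votes <- matrix(0, nrow(test_x), length(lev),
                      dimnames = list(NULL, lev))
      with_seed(seed, {
        for (m in seq_len(hp$n_learners)) {
          cols <- sample(d, sdim)
          pred_m <- if (hp$base == "lda") {
            tryCatch(
              lda_predict(xs[, cols, drop = FALSE], train_y,
                          ts[, cols, drop = FALSE]),
              error = function(e) NULL)
          } else {
            knn_predict(xs[, cols, drop = FALSE], train_y,
                        ts[, cols, drop = FALSE], k = 1L)
          }
          if (!is.null(pred_m)) {
            votes[cbind(seq_len(nrow(votes)), match(pred_m, lev))] <-
              votes[cbind(seq_len(nrow(votes)), match(pred_m, lev))] + 1
          }
        }
      })
      factor(lev[max.col(votes, ties.method = "first")], levels = lev)
    }
  )
}
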