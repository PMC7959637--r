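# Experiment harness: run a classifier roster under a protocol and report
# the metric suite, plus the feature-count sweep.

#' Run a classification experiment
#'
#' Applies an optional entropy selection to the features, then evaluates
#' each classifier in the roster under the chosen protocol. Under
#' `"cv10"` (stratified k-fold), out-of-fold predictions are pooled into one
#' confusion matrix per classifier — every sample is predicted exactly
#' once. Under `"holdout5050"` a stratified split trains on one half and
#' scores the other.
#'
#' @param features Numeric feature matrix (rows = images).
#' @param labels Class labels, one per row.
#' @param roster List of [classifier_spec()]s or roster names.
#' @param selection Optional `selection_result` from [select_by_entropy()];
#'   `NULL` uses all features.
#' @param protocol `"cv10"` or `"holdout5050"`.
#' @param k Folds for the CV protocol (default 10).
#' @param train_fraction Training fraction for the holdout protocol
#'   (default 0.5).
#' @param seed Integer seed driving splits and ensemble draws.
#'
#' @return List of `metrics_report`s, in roster order.
#' @export
run_experiment <- function(features, labels, roster = list("cubic_svm"),
                           selection = NULL,
                           protocol = c("cv10", "holdout5050"),
                           k = 10L, train_fraction = 0.5, seed = 1L) {
  protocol <- match.arg(protocol)
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stopf("feature rows (%d) and labels (%d) differ", nrow(features), length(labels))
  }
  labels <- droplevels(as.factor(labels))
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "selection_result"))
    features <- features[, selection$selected_indices, drop = FALSE]
  }
  roster <- lapply(roster, function(s) {
    if (is.character(s)) classifier_spec(s) else s
  })
  classes <- levels(labels)
  folds <- if (protocol == "cv10") {
    make_cv_folds(labels, k = k, seed = seed)
  } else {
    list(make_holdout_split(labels, train_fraction = train_fraction, seed = seed))
  }
  lapply(roster, function(spec) {
    pred <- factor(rep(NA_character_, length(labels)), levels = classes)
    for (f in seq_along(folds)) {
      fold <- folds[[f]]
      pred[fold$test] <- train_and_predict(
        features[fold$train, , drop = FALSE], labels[fold$train],
        features[fold$test, , drop = FALSE], spec,
        seed = derive_seed(seed, f))
    }
    scored <- !is.na(pred)  # holdout scores the test half only
    compute_metrics(
      confusion_matrix(labels[scored], pred[scored], classes = classes),
      classifier = spec)
  })
}

#' Sweep accuracy over feature-count selections
#'
#' Re-runs one classifier while retaining the first `n` features of the
#' entropy-sorted order for each requested count, reporting accuracy per
#' count — the layout of a feature-count/accuracy table.
#'
#' @param features Numeric feature matrix.
#' @param labels Class labels.
#' @param counts Integer vector of feature counts to evaluate.
#' @param spec Classifier to use (default cubic SVM).
#' @param entropy Optional precomputed `entropy_vector`.
#' @param order Entropy sort order (default ascending).
#' @param protocol,k,seed Passed to [run_experiment()].
#'
#' @return data.frame with columns `n_features` and `accuracy`.
#' @export
selection_sweep <- function(features, labels, counts,
                            spec = classifier_spec("cubic_svm"),
                            entropy = NULL, order = "ascending",
                            protocol = "cv10", k = 10L, seed = 1L) {
  features <- as.matrix(features)
  if (is.null(entropy)) entropy <- feature_entropy(features)
  d <- ncol(features)
  counts <- as.integer(counts)
  if (any(counts < 1 | counts > d)) {
    stopf("counts must lie in [1, %d]", d)
  }
  acc <- vapply(counts, function(nf) {
    sel <- select_by_entropy(features, entropy, fraction = nf / d, order = order)
    # fraction rounding could shift by one; force the exact count
    sel$selected_indices <- sel$selected_indices[seq_len(nf)]
    rep <- run_experiment(features, labels, roster = list(spec),
                          selection = sel, protocol = protocol,
                          k = k, seed = seed)[[1]]
    rep$accuracy
  }, numeric(1))
  data.frame(n_features = counts, accuracy = acc)
}
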