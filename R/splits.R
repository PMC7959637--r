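# Stratified data-division protocols: 50:50 holdout and k-fold CV.

#' Stratified holdout split
#'
#' Partitions indices into disjoint, exhaustive train/test sets, stratified
#' by class: for each class, `round(n_c * train_fraction)` samples go to
#' training, so per-class counts differ by at most 1 between halves at the
#' default 50:50 division.
#'
#' @param labels Class labels (factor or character).
#' @param train_fraction Fraction of each class used for training
#'   (default 0.5).
#' @param seed Integer seed.
#'
#' @return List with integer vectors `train` and `test`.
#' @export
make_holdout_split <- function(labels, train_fraction = 0.5, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 2)) {
    stopf("stratification error: class(es) with fewer than 2 samples: %s",
          paste(names(counts)[counts < 2], collapse = ", "))
  }
  with_seed(seed, {
    train <- integer(0)
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      n_train <- as.integer(round_half_away(length(idx) * train_fraction))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_train))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Stratified k-fold cross-validation folds
#'
#' Each sample appears in exactly one test fold; per-fold class proportions
#' match the global proportions to within one sample per class.
#'
#' @param labels Class labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#'
#' @return List of `k` lists, each with integer vectors `train` and `test`.
#' @export
make_cv_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k > n) stopf("config error: k = %d exceeds sample count %d", k, n)
  if (k < 2) stopf("config error: k must be >= 2")
  counts <- table(labels)
  if (any(counts < k)) {
    warnf("class(es) with fewer than %d samples (%s): stratification is partial",
          k, paste(names(counts)[counts < k], collapse = ", "))
  }
  with_seed(seed, {
    fold_of <- integer(n)
    for (cls in levels(labels)) {
      idx <- sample(which(labels == cls))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) {
      test <- which(fold_of == f)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
}
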