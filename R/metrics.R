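# Confusion matrices and the metric suite: sensitivity, specificity, FNR,
# accuracy (all percent) and F-score, macro-averaged one-vs-rest.

#' Build a confusion matrix from true and predicted labels
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class order (default the union of levels).
#' @return A `confusion_matrix`: integer matrix with true classes as rows,
#'   predictions as columns.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted must have equal length")
  }
  if (is.null(classes)) {
    classes <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  }
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = classes)
  counts <- table(truth = truth, predicted = predicted)
  structure(unclass(counts), class = "confusion_matrix")
}

#' Compute the metric suite from a confusion matrix
#'
#' Per class (one-vs-rest): sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), precision = TP/(TP+FP), and FNR = 100 − sensitivity (the
#' identity holds exactly by construction). Report-level sensitivity,
#' specificity, FNR and precision are unweighted macro-averages over
#' classes; accuracy is trace/total; the F-score is `2PR/(P+R)` on macro
#' precision P and macro recall R. Percentages are on the 0–100 scale,
#' F-score on 0–1. A class with no true samples contributes recall 0 with a
#' warning.
#'
#' @param cm A [confusion_matrix()] (square count matrix).
#' @param classifier Optional [classifier_spec()] recorded in the report.
#' @return A `metrics_report`: list with fields `sensitivity`,
#'   `specificity`, `fnr`, `accuracy`, `f_score`, `per_class` (data.frame),
#'   `confusion`, `classifier`.
#' @export
compute_metrics <- function(cm, classifier = NULL) {
  m <- unclass(as.matrix(cm))
  if (nrow(m) != ncol(m)) stopf("confusion matrix must be square")
  total <- sum(m)
  if (total <= 0) stopf("confusion matrix is empty")
  classes <- rownames(m)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(m)))
  tp <- diag(m)
  support <- rowSums(m)
  predicted <- colSums(m)
  fn <- support - tp
  fp <- predicted - tp
  tn <- total - tp - fn - fp
  if (any(support == 0)) {
    warnf("class(es) with no true samples: %s; recall defined as 0",
          paste(classes[support == 0], collapse = ", "))
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  sens <- 100 * safe_div(tp, tp + fn)
  spec <- 100 * safe_div(tn, tn + fp)
  prec <- 100 * safe_div(tp, tp + fp)
  per_class <- data.frame(
    class = classes, support = as.integer(support),
    sensitivity = sens, specificity = spec,
    fnr = 100 - sens, precision = prec, stringsAsFactors = FALSE)
  macro_sens <- mean(sens)
  macro_prec <- mean(prec)
  f <- if (macro_prec + macro_sens > 0) {
    2 * (macro_prec / 100) * (macro_sens / 100) /
      ((macro_prec + macro_sens) / 100)
  } else 0
  structure(
    list(sensitivity = macro_sens,
         specificity = mean(spec),
         fnr = 100 - macro_sens,
         accuracy = 100 * sum(tp) / total,
         f_score = f,
         per_class = per_class,
         confusion = m,
         classifier = classifier),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  nm <- if (!is.null(x$classifier)) x$classifier$name else "classifier"
  cat(sprintf("%s: sensitivity %.1f%%  specificity %.1f%%  FNR %.1f%%  accuracy %.1f%%  F-score %.3f\n",
              nm, x$sensitivity, x$specificity, x$fnr, x$accuracy, x$f_score))
  invisible(x)
}

#' Tabulate a list of metric reports
#'
#' One row per classifier with the metric suite at table precision
#' (percentages to one decimal, F-score to three).
#'
#' @param reports List of `metrics_report`s.
#' @return A data.frame shaped like the result tables.
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      classifier = if (!is.null(r$classifier)) r$classifier$name else NA_character_,
      sensitivity = round(r$sensitivity, 1),
      specificity = round(r$specificity, 1),
      fnr = round(r$fnr, 1),
      accuracy = round(r$accuracy, 1),
      f_score = round(r$f_score, 3),
      stringsAsFactors = FALSE)
  }))
}
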