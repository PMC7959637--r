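# Entropy scoring of fused features and fraction-based selection.
#
# Each feature column is scored by the Shannon entropy of its empirical
# histogram over n_bins equal-width bins spanning that column's own range.
# Low-entropy columns are nearly constant; high-entropy columns spread
# across their range. Selection sorts by entropy and keeps the first
# fraction of the sorted order.

#' Per-feature histogram entropy
#'
#' For each feature column: build a histogram over `n_bins` equal-width bins
#' spanning that column's \[min, max\], convert counts to probabilities
#' `p_i = count_i / n`, and return the Shannon entropy
#' `H = -sum(p_i log2 p_i)` (with `0 log 0 := 0`), in bits. A constant
#' column occupies a single bin and scores exactly 0; the maximum attainable
#' score is `log2(n_bins)`.
#'
#' @param features Numeric matrix (e.g. a `fused_features`), >= 2 rows.
#' @param n_bins Number of histogram bins (default 256).
#'
#' @return An `entropy_vector`: numeric vector of length `ncol(features)`
#'   with attribute `n_bins`.
#' @export
feature_entropy <- function(features, n_bins = 256L) {
  features <- as.matrix(features)
  if (nrow(features) < 2) {
    stopf("insufficient data: entropy needs >= 2 rows, got %d", nrow(features))
  }
  if (n_bins < 2) stopf("n_bins must be >= 2")
  if (!all(is.finite(features))) stopf("data error: non-finite feature values")
  n <- nrow(features)
  h <- vapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    lo <- min(x); hi <- max(x)
    if (lo == hi) return(0)
    # equal-width bins over [lo, hi]; right-closed, max value into last bin
    bin <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    p <- tabulate(bin, nbins = n_bins) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  structure(h, class = "entropy_vector", n_bins = as.integer(n_bins))
}

#' Select features by entropy rank
#'
#' Sorts features by entropy — ascending by default — breaking ties by
#' ascending column index, and retains the first
#' `max(1, round(fraction * D))` of the sorted order (half-away-from-zero
#' rounding, so a 0.5 fraction of 10,240 fused features keeps exactly
#' 5,120). Under `"ascending"` every retained feature's entropy is less than
#' or equal to every discarded feature's; `"descending"` keeps the
#' highest-entropy features instead.
#'
#' @param features Numeric feature matrix.
#' @param entropy An `entropy_vector` from [feature_entropy()] (computed if
#'   omitted), length equal to `ncol(features)`.
#' @param fraction Fraction of features to keep, in (0, 1\].
#' @param order `"ascending"` (default) or `"descending"`.
#' @param n_bins Bins used if `entropy` must be computed.
#'
#' @return A `selection_result`: list with `selected_indices` (in sort
#'   order), `entropy`, `fraction`, `order`, and `reduced` (the selected
#'   columns of `features`, in selected order).
#' @export
select_by_entropy <- function(features, entropy = NULL, fraction = 0.5,
                              order = c("ascending", "descending"),
                              n_bins = 256L) {
  order <- match.arg(order)
  features <- as.matrix(features)
  if (is.null(entropy)) entropy <- feature_entropy(features, n_bins)
  if (length(entropy) != ncol(features)) {
    stopf("entropy length %d does not match feature count %d",
          length(entropy), ncol(features))
  }
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 || fraction > 1) {
    stopf("config error: fraction must lie in (0, 1]")
  }
  d <- ncol(features)
  key <- if (order == "ascending") as.numeric(entropy) else -as.numeric(entropy)
  perm <- order(key, seq_len(d))  # stable: ties broken by ascending index
  k <- max(1L, as.integer(round_half_away(fraction * d)))
  sel <- perm[seq_len(k)]
  structure(
    list(selected_indices = sel,
         entropy = entropy,
         fraction = fraction,
         order = order,
         reduced = features[, sel, drop = FALSE]),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d of %d features (%.0f%%), %s entropy order\n",
              length(x$selected_indices), length(x$entropy),
              100 * x$fraction, x$order))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Persists indices, entropies and configuration so an experiment can be
#' replayed exactly.
#'
#' @param x A `selection_result`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  jsonlite::write_json(
    list(selected_indices = x$selected_indices,
         entropy = as.numeric(x$entropy),
         n_bins = attr(x$entropy, "n_bins"),
         fraction = x$fraction,
         order = x$order),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a selection result back from JSON
#'
#' @param path File written by [write_selection_json()].
#' @return A list with the stored fields (no feature matrix attached).
#' @export
read_selection_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
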