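# Core transform: truncate -> segment -> inverse-vectorize -> binarize,
# plus expansion of binary images to CNN-sized 3-channel inputs.

#' Construct a binary image
#'
#' @param pixels Numeric matrix with entries in {0, 1} (default 32x32).
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!all(pixels %in% c(0, 1))) {
    stopf("binary_image entries must be strictly 0 or 1")
  }
  structure(list(pixels = pixels), class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("binary_image %dx%d, %d of %d pixels set\n",
              nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), length(x$pixels)))
  invisible(x)
}

#' Construct a labelled image set
#'
#' @param images List of [binary_image()]s.
#' @param labels Rhythm-class labels, one per image.
#' @param source_record Identifier of the originating record.
#' @param segment_indices 0-based segment indices, one per image.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, source_record, segment_indices) {
  if (length(images) != length(labels) ||
      length(images) != length(segment_indices)) {
    stopf("images, labels and segment_indices must have equal length")
  }
  structure(
    list(images = images,
         labels = labels,
         source_record = as.character(source_record),
         segment_indices = as.integer(segment_indices)),
    class = "labeled_image_set"
  )
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled_image_set '%s': %d image(s); labels: %s\n",
              x$source_record, length(x$images),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Truncate a signal to a whole number of segments
#'
#' Returns the first `segment_length * floor(n / segment_length)` samples;
#' never pads. A 127,356-sample record at the default segment length 1,024
#' loses its trailing 380 samples, leaving 126,976. A record shorter than one
#' segment yields an empty vector with a warning (unusable record).
#'
#' @param signal Numeric vector.
#' @param segment_length Samples per segment (default 1024).
#' @return The truncated signal.
#' @export
truncate_to_multiple <- function(signal, segment_length = 1024L) {
  if (segment_length <= 0) stopf("segment_length must be positive")
  n <- length(signal)
  keep <- segment_length * (n %/% segment_length)
  if (keep == 0) {
    warnf("signal of %d samples is shorter than one %d-sample segment; record unusable",
          n, segment_length)
    return(signal[0])
  }
  signal[seq_len(keep)]
}

#' Split a signal into consecutive non-overlapping segments
#'
#' @param signal Numeric vector whose length is a multiple of
#'   `segment_length` (apply [truncate_to_multiple()] first).
#' @param segment_length Samples per segment (default 1024).
#' @return A list of numeric vectors in temporal order; element `i` carries
#'   0-based segment index `i - 1`.
#' @export
segment_signal <- function(signal, segment_length = 1024L) {
  if (segment_length <= 0) stopf("segment_length must be positive")
  n <- length(signal)
  if (n %% segment_length != 0) {
    stopf("signal length %d is not a multiple of %d; apply truncate_to_multiple() first",
          n, segment_length)
  }
  k <- n %/% segment_length
  lapply(seq_len(k), function(i) {
    signal[((i - 1L) * segment_length + 1L):(i * segment_length)]
  })
}

#' Inverse vectorization of a segment into a matrix
#'
#' The inverse of column-stacking vectorization: entry (i, j) (1-based) of
#' the result is element `(j - 1) * rows + i` of the segment, so
#' re-vectorizing column-by-column returns the segment exactly. A 1,024-long
#' segment with `rows = cols = 32` becomes the 32x32 matrix the pipeline
#' binarizes.
#'
#' @param segment Numeric vector of length `rows * cols`.
#' @param rows,cols Output dimensions (default 32x32).
#' @param order `"column"` (the vectorization inverse, default) or `"row"`
#'   for sensitivity analysis.
#' @return A `rows` x `cols` numeric matrix.
#' @export
devectorize <- function(segment, rows = 32L, cols = 32L,
                        order = c("column", "row")) {
  order <- match.arg(order)
  if (rows * cols != length(segment)) {
    stopf("shape error: %d x %d != segment length %d", rows, cols, length(segment))
  }
  if (order == "column") matrix(segment, nrow = rows, ncol = cols)
  else matrix(segment, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Binarize a numeric matrix into a binary image
#'
#' Default method `"minmax"`: rescale the matrix to \[0, 1\] by its own
#' minimum and maximum, then set pixel to 1 where the scaled value strictly
#' exceeds `threshold`. A constant matrix maps to all zeros. Method `"mean"`
#' thresholds at the matrix mean instead (ignoring `threshold`). Min-max
#' scaling makes the result invariant to positive affine rescaling of the
#' input, so images do not depend on signal amplitude calibration.
#'
#' @param mat Numeric matrix with finite entries.
#' @param method `"minmax"` or `"mean"`.
#' @param threshold Fraction in \[0, 1\] for `"minmax"` (default 0.5); a
#'   scaled value exactly equal to the threshold maps to 0.
#' @return A [binary_image()] of the same dimensions.
#' @export
binarize <- function(mat, method = c("minmax", "mean"), threshold = 0.5) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stopf("data error: matrix has non-finite entries")
  if (method == "minmax") {
    rng <- range(mat)
    if (rng[1] == rng[2]) {
      px <- matrix(0, nrow(mat), ncol(mat))
    } else {
      scaled <- (mat - rng[1]) / (rng[2] - rng[1])
      px <- (scaled > threshold) * 1
    }
  } else {
    px <- (mat > mean(mat)) * 1
  }
  binary_image(px)
}

#' Expand a binary image to a CNN-sized three-channel input
#'
#' Grayscale intensity is `255 * pixel`; spatial upscaling uses
#' nearest-neighbour interpolation (keeping values strictly in {0, 255});
#' the three channels are identical copies.
#'
#' @param image A [binary_image()].
#' @param side Target side length, one of `sides` (224 for AlexNet/VGG19
#'   input geometry, 299 for Inception-v3).
#' @param sides Permitted side lengths.
#' @return A `side x side x 3` numeric array with entries in {0, 255},
#'   classed `model_input`.
#' @export
to_model_input <- function(image, side = 224L, sides = c(224L, 299L)) {
  stopifnot(inherits(image, "binary_image"))
  if (!side %in% sides) {
    stopf("config error: side %d not in supported set {%s}",
          side, paste(sides, collapse = ", "))
  }
  src <- image$pixels
  n_src <- nrow(src)
  m_src <- ncol(src)
  # nearest neighbour: target pixel centre maps back to source index
  ri <- pmin(floor((seq_len(side) - 0.5) * n_src / side) + 1L, n_src)
  ci <- pmin(floor((seq_len(side) - 0.5) * m_src / side) + 1L, m_src)
  gray <- 255 * src[ri, ci, drop = FALSE]
  out <- array(gray, dim = c(side, side, 3))
  structure(out, class = "model_input")
}

#' Transform a full ECG record into labelled binary images
#'
#' The pipeline's signal-to-image stage: take one lead, truncate to a whole
#' number of segments, split, inverse-vectorize each segment to a square
#' matrix, and binarize. A 127,356-sample record yields 124 images at the
#' defaults. Labels come from [assign_segment_labels()]; segments labelled
#' `NA` under the `"majority"` policy are dropped.
#'
#' @param record An [ecg_record()].
#' @param lead Lead index to use (default 1).
#' @param segment_length Samples per segment (default 1024).
#' @param side Image side; `side^2` must equal `segment_length`.
#' @param method,threshold Binarization settings, see [binarize()].
#' @param order Reshape order, see [devectorize()].
#' @param policy,annotations,symbol_map Labelling settings, see
#'   [assign_segment_labels()].
#' @return A [labeled_image_set()].
#' @export
transform_record <- function(record, lead = 1L, segment_length = 1024L,
                             side = 32L, method = "minmax", threshold = 0.5,
                             order = "column",
                             policy = "record", annotations = NULL,
                             symbol_map = default_symbol_map()) {
  stopifnot(inherits(record, "ecg_record"))
  if (side * side != segment_length) {
    stopf("shape error: side^2 (%d) must equal segment_length (%d)",
          side * side, segment_length)
  }
  signal <- truncate_to_multiple(record$signals[[lead]], segment_length)
  segments <- segment_signal(signal, segment_length)
  labels <- assign_segment_labels(record, annotations, segment_length,
                                  policy, symbol_map)
  images <- lapply(segments, function(s) {
    binarize(devectorize(s, side, side, order), method, threshold)
  })
  keep <- !is.na(labels)
  labeled_image_set(images = images[keep],
                    labels = labels[keep],
                    source_record = record$record_id,
                    segment_indices = which(keep) - 1L)
}
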