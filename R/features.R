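# Fixed-length per-image features from pluggable backends, fused by
# concatenation. The pretrained CNN backends (AlexNet FC7, VGG19 FC7,
# Inception-v3 avg-pool) are declared with their published output geometry;
# running them requires a deep-learning runtime with their ImageNet weights,
# which this package does not ship, so extraction through them raises an
# explicit environment error. The stub backend — a fixed, seeded random
# linear projection of the flattened image followed by a clamp-at-zero
# nonlinearity — is fully deterministic, needs no download, and preserves
# image geometry well enough (Johnson-Lindenstrauss) for the downstream
# selection and classification stages to be exercised end to end.

#' Describe a feature-extraction backend
#'
#' @param name One of `"alexnet_fc7"`, `"vgg19_fc7"`,
#'   `"inceptionv3_avgpool"`, `"stub"`. The three CNN names fix
#'   `output_dim`/`input_side` to their published geometry (4096/224,
#'   4096/224, 2048/299); the stub accepts any positive `output_dim`.
#' @param output_dim Feature dimensionality (stub only; others fixed).
#' @param input_side Expected image side (stub default 32: it consumes the
#'   binary images directly).
#' @param stub_seed Seed fixing the stub's random projection (stub only).
#'
#' @return An object of class `backend_spec`.
#' @export
backend_spec <- function(name = c("stub", "alexnet_fc7", "vgg19_fc7",
                                  "inceptionv3_avgpool"),
                         output_dim = NULL, input_side = NULL,
                         stub_seed = 1L) {
  name <- match.arg(name)
  known <- list(
    alexnet_fc7         = list(output_dim = 4096L, input_side = 224L),
    vgg19_fc7           = list(output_dim = 4096L, input_side = 224L),
    inceptionv3_avgpool = list(output_dim = 2048L, input_side = 299L)
  )
  if (name %in% names(known)) {
    k <- known[[name]]
    if (!is.null(output_dim) && output_dim != k$output_dim) {
      stopf("%s has fixed output_dim %d", name, k$output_dim)
    }
    output_dim <- k$output_dim
    input_side <- k$input_side
  } else {
    if (is.null(output_dim)) output_dim <- 4096L
    if (is.null(input_side)) input_side <- 32L
    if (output_dim < 1) stopf("stub output_dim must be positive")
  }
  structure(
    list(name = name, output_dim = as.integer(output_dim),
         input_side = as.integer(input_side),
         stub_seed = as.integer(stub_seed)),
    class = "backend_spec"
  )
}

#' @export
print.backend_spec <- function(x, ...) {
  cat(sprintf("backend_spec %s: %d features, input side %d%s\n",
              x$name, x$output_dim, x$input_side,
              if (x$name == "stub") sprintf(", seed %d", x$stub_seed) else ""))
  invisible(x)
}

#' @noRd
flatten_image <- function(img, expected_side) {
  if (inherits(img, "binary_image")) {
    px <- img$pixels
    if (nrow(px) != expected_side || ncol(px) != expected_side) {
      stopf("shape error: image side %d does not match backend input side %d",
            nrow(px), expected_side)
    }
    as.numeric(px)
  } else if (inherits(img, "model_input")) {
    d <- dim(img)
    if (d[1] != expected_side) {
      stopf("shape error: image side %d does not match backend input side %d",
            d[1], expected_side)
    }
    as.numeric(img[, , 1]) / 255
  } else {
    stopf("images must be binary_image or model_input objects")
  }
}

#' Extract per-image features through a backend
#'
#' Returns one feature row per image, in input order. The stub backend
#' computes `relu(x W + b)` where `x` is the flattened image (values in
#' \[0, 1\]), and `W`, `b` are drawn once from a seeded standard normal
#' scaled by `1/sqrt(d_in)` — the same seed always yields the same
#' projection. Pretrained backends raise an environment error directing to
#' the stub, since their weights are not shipped.
#'
#' @param images List of [binary_image()] or `model_input` objects whose
#'   side matches `spec$input_side`.
#' @param spec A [backend_spec()].
#' @param image_ids Optional identifiers, one per image.
#'
#' @return A `feature_matrix`: numeric matrix `n_images x output_dim` with
#'   attributes `backend` (the spec) and `image_ids`.
#' @export
extract_features <- function(images, spec, image_ids = NULL) {
  stopifnot(inherits(spec, "backend_spec"))
  if (spec$name != "stub") {
    stopf(paste0("environment error: pretrained weights for backend '%s' are ",
                 "not available in this installation; use the 'stub' backend ",
                 "(backend_spec('stub', output_dim = %d))"),
          spec$name, spec$output_dim)
  }
  n <- length(images)
  if (n == 0) stopf("no images supplied")
  x <- t(vapply(images, flatten_image, numeric(spec$input_side^2),
                expected_side = spec$input_side))
  d_in <- ncol(x)
  proj <- with_seed(spec$stub_seed, {
    list(W = matrix(stats::rnorm(d_in * spec$output_dim, sd = 1 / sqrt(d_in)),
                    nrow = d_in),
         b = stats::rnorm(spec$output_dim, sd = 0.1))
  })
  f <- x %*% proj$W
  f <- sweep(f, 2, proj$b, "+")
  f <- pmax(f, 0)
  if (is.null(image_ids)) image_ids <- sprintf("img%05d", seq_len(n))
  feature_matrix(f, spec, image_ids)
}

#' Construct a feature matrix
#'
#' @param values Numeric matrix, one row per image.
#' @param backend The [backend_spec()] that produced it.
#' @param image_ids Identifiers, one per row.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, backend, image_ids) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stopf("feature matrix has non-finite entries")
  if (ncol(values) != backend$output_dim) {
    stopf("column count %d does not match backend output_dim %d",
          ncol(values), backend$output_dim)
  }
  if (length(image_ids) != nrow(values)) {
    stopf("image_ids length must match row count")
  }
  structure(values, class = c("feature_matrix", "matrix"),
            backend = backend, image_ids = as.character(image_ids))
}

#' Fuse feature blocks by horizontal concatenation
#'
#' Concatenates the blocks column-wise in the given order, checking that all
#' blocks describe the same images in the same order. With the three CNN
#' geometries (4096 + 4096 + 2048) the fused width is 10,240.
#'
#' @param blocks Non-empty list of `feature_matrix` objects with identical
#'   `image_ids`.
#' @return A `fused_features` matrix with attributes `block_boundaries`
#'   (data.frame of backend, start, end — 1-based inclusive columns) and
#'   `image_ids`.
#' @export
fuse_features <- function(blocks) {
  if (!is.list(blocks) || length(blocks) == 0) {
    stopf("contract error: fuse_features needs at least one block")
  }
  ids <- attr(blocks[[1]], "image_ids")
  for (b in blocks) {
    if (!inherits(b, "feature_matrix")) stopf("blocks must be feature_matrix objects")
    if (nrow(b) != nrow(blocks[[1]]) || !identical(attr(b, "image_ids"), ids)) {
      stopf("alignment error: blocks disagree on images (row count or ids)")
    }
  }
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  fused <- do.call(cbind, lapply(blocks, unclass))
  boundaries <- data.frame(
    backend = vapply(blocks, function(b) attr(b, "backend")$name, character(1)),
    start = starts, end = as.integer(ends), stringsAsFactors = FALSE)
  structure(fused, class = c("fused_features", "matrix"),
            block_boundaries = boundaries, image_ids = ids)
}
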