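# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a root seed and an index, staying inside the
# 32-bit integer range R requires of set.seed().
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

# round() in R is banker's rounding; selection sizes use half-away-from-zero.
#' @noRd
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Names of the four rhythm classes, in canonical order.
#' Rhythm classes recognised by the pipeline
#'
#' The pipeline distinguishes normal sinus rhythm (`NSR`), monomorphic
#' ventricular tachycardia (`VT`), ventricular fibrillation (`VFIB`) and
#' ventricular flutter (`VFL`).
#'
#' @return Character vector of the four class names, in canonical order.
#' @export
rhythm_classes <- function() c("NSR", "VT", "VFIB", "VFL")

#' @noRd
as_rhythm_class <- function(x) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), rhythm_classes())
  if (length(bad) > 0) {
    stopf("unknown rhythm class(es): %s", paste(bad, collapse = ", "))
  }
  factor(x, levels = rhythm_classes())
}
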