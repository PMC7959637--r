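# Record container, WFDB-dialect reader/writer, annotations, segment labels.

#' Construct an ECG record
#'
#' @param record_id Record identifier string.
#' @param signals List of numeric vectors, one per lead, all the same length.
#' @param sampling_rate Sampling frequency in Hz.
#' @param lead_names Character vector of lead names, one per signal.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signals, sampling_rate, lead_names = NULL) {
  if (!is.list(signals) || length(signals) == 0) {
    stopf("signals must be a non-empty list of numeric vectors")
  }
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) != 1) {
    stopf("all leads must have the same length (got %s)",
          paste(lens, collapse = ", "))
  }
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_along(signals))
  if (length(lead_names) != length(signals)) {
    stopf("lead_names must match the number of signals")
  }
  structure(
    list(record_id = as.character(record_id),
         signals = lapply(signals, as.numeric),
         sampling_rate = sampling_rate,
         lead_names = as.character(lead_names)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cls <- attr(x, "rhythm_class")
  cat(sprintf("ecg_record '%s': %d lead(s) [%s], %d samples @ %g Hz%s\n",
              x$record_id, length(x$signals),
              paste(x$lead_names, collapse = ", "),
              length(x$signals[[1]]), x$sampling_rate,
              if (is.null(cls)) "" else paste0(", rhythm ", cls)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$signals[[1]])

# ---------------------------------------------------------------------------
# WFDB dialect. Header: "<record> <nsig> <fs> <nsamp>" then one line per
# signal "<file> <format> <gain>(<baseline>)/<units> <adcres> <adczero>
# <initval> <cksum> <bsize> <description>". Signal formats 16 (16-bit
# little-endian two's complement) and 212 (two 12-bit samples in 3 bytes)
# are supported for reading; the writer emits format 16. Samples are
# multiplexed frame by frame. physical = (digital - baseline) / gain.
# ---------------------------------------------------------------------------

#' Write an ECG record in minimal WFDB-compatible form
#'
#' Emits `<record>.hea` (text header) and `<record>.dat` (16-bit signed
#' little-endian samples, multiplexed by frame) into `dir`. Physical values
#' are digitised as `round(x * gain)` with baseline 0 and clamped to the
#' 16-bit range.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param gain ADC gain in units per millivolt-like unit (default 200).
#'
#' @return Invisibly, the header path.
#' @export
write_wfdb <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_sig <- length(record$signals)
  n <- length(record$signals[[1]])
  dat_name <- paste0(record$record_id, ".dat")
  digital <- vapply(record$signals, function(s) {
    d <- round(s * gain)
    pmin(pmax(d, -32768), 32767)
  }, numeric(n))
  # multiplex: frame-major (sample 1 of all leads, then sample 2, ...)
  interleaved <- as.integer(t(digital))
  con <- file(file.path(dir, dat_name), "wb")
  on.exit(close(con))
  writeBin(interleaved, con, size = 2L, endian = "little")
  hdr <- c(
    sprintf("%s %d %g %d", record$record_id, n_sig, record$sampling_rate, n),
    sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s",
            dat_name, gain, as.integer(digital[1, ]), record$lead_names)
  )
  hea_path <- file.path(dir, paste0(record$record_id, ".hea"))
  writeLines(hdr, hea_path)
  invisible(hea_path)
}

#' @noRd
parse_signal_spec <- function(line) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(f) < 2) stopf("format error in header signal line: '%s'", line)
  fmt <- as.integer(sub("x.*$", "", f[2]))  # strip samples-per-frame suffix
  gain_field <- if (length(f) >= 3) f[3] else "200"
  gain_field <- sub("/.*$", "", gain_field)
  baseline <- 0
  if (grepl("\\(", gain_field)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    gain_field <- sub("\\(.*$", "", gain_field)
  }
  gain <- as.numeric(gain_field)
  if (is.na(gain) || gain == 0) gain <- 200
  adczero <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
  if (!grepl("\\(", f[3] %||% "")) baseline <- ifelse(is.na(adczero), 0, adczero)
  desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA_character_
  list(file = f[1], format = fmt, gain = gain, baseline = baseline, desc = desc)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @noRd
decode_format16 <- function(path, n_sig, n_samples) {
  expected <- 2 * n_sig * n_samples
  actual <- file.size(path)
  if (is.na(actual) || actual < expected) {
    stopf("format error in '%s': expected %d bytes (%d samples x %d leads), found %s",
          path, expected, n_samples, n_sig, ifelse(is.na(actual), "none", actual))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, integer(), n = n_sig * n_samples, size = 2L,
                      signed = TRUE, endian = "little")
  matrix(raw_vals, nrow = n_sig)  # column = frame
}

#' @noRd
decode_format212 <- function(path, n_sig, n_samples) {
  total <- n_sig * n_samples
  expected <- ceiling(total * 1.5)
  actual <- file.size(path)
  if (is.na(actual) || actual < expected) {
    stopf("format error in '%s': expected %d bytes for %d 12-bit samples, found %s",
          path, expected, total, ifelse(is.na(actual), "none", actual))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- as.integer(readBin(con, "raw", n = expected))
  n_pairs <- ceiling(total / 2)
  b1 <- bytes[seq(1, by = 3, length.out = n_pairs)]
  b2 <- bytes[seq(2, by = 3, length.out = n_pairs)]
  b3 <- bytes[seq(3, by = 3, length.out = n_pairs)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8)
  s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4), 0x0FL), 8)
  s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
  s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
  vals <- as.vector(rbind(s1, s2))[seq_len(total)]
  matrix(vals, nrow = n_sig)
}

#' Read a WFDB record
#'
#' Parses the text header, decodes the signal file (formats 16 and 212) and
#' applies each lead's gain and baseline, returning physical units. Lead
#' order follows the header. A missing or short signal file raises a format
#' error naming the file rather than silently truncating.
#'
#' @param header_path Path to the `.hea` header file.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(header_path) {
  if (!file.exists(header_path)) {
    stopf("format error: header file '%s' not found", header_path)
  }
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(head_f) < 4) {
    stopf("format error in '%s': record line needs name, n_sig, fs, n_samples",
          header_path)
  }
  record_id <- sub("/.*$", "", head_f[1])
  n_sig <- as.integer(head_f[2])
  fs <- as.numeric(head_f[3])
  n_samples <- as.integer(head_f[4])
  if (length(lines) < 1 + n_sig) {
    stopf("format error in '%s': %d signal lines declared, %d present",
          header_path, n_sig, length(lines) - 1L)
  }
  specs <- lapply(lines[2:(1 + n_sig)], parse_signal_spec)
  files <- unique(vapply(specs, `[[`, character(1), "file"))
  if (length(files) != 1) {
    stopf("format error in '%s': multi-file records are not supported", header_path)
  }
  fmt <- unique(vapply(specs, `[[`, numeric(1), "format"))
  if (length(fmt) != 1 || !fmt %in% c(16, 212)) {
    stopf("format error in '%s': unsupported signal format %s",
          header_path, paste(fmt, collapse = ","))
  }
  dat_path <- file.path(dirname(header_path), files)
  if (!file.exists(dat_path)) {
    stopf("format error: signal file '%s' not found", dat_path)
  }
  digital <- if (fmt == 16) decode_format16(dat_path, n_sig, n_samples)
             else decode_format212(dat_path, n_sig, n_samples)
  signals <- lapply(seq_len(n_sig), function(i) {
    (digital[i, ] - specs[[i]]$baseline) / specs[[i]]$gain
  })
  lead_names <- vapply(seq_len(n_sig), function(i) {
    specs[[i]]$desc %||% paste0("lead", i)
  }, character(1))
  ecg_record(record_id, signals, fs, lead_names)
}

# ---------------------------------------------------------------------------
# Annotations and segment labels
# ---------------------------------------------------------------------------

#' Construct an annotation set
#'
#' Rhythm annotations as (sample index, symbol) events: each event's symbol
#' applies from its sample index until the next event.
#'
#' @param record_id Record the annotations belong to.
#' @param sample Integer vector of 0-based sample indices, non-decreasing.
#' @param symbol Character vector of annotation symbols (e.g. `"(N"`,
#'   `"(VT"`), same length as `sample`.
#'
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(record_id, sample, symbol) {
  sample <- as.integer(sample)
  if (length(sample) != length(symbol)) {
    stopf("sample and symbol must have the same length")
  }
  if (is.unsorted(sample)) stopf("annotation sample indices must be non-decreasing")
  structure(
    list(record_id = as.character(record_id),
         events = data.frame(sample = sample, symbol = as.character(symbol),
                             stringsAsFactors = FALSE)),
    class = "annotation_set"
  )
}

#' Read annotations from a plain-text table
#'
#' Expects whitespace-separated columns `sample symbol` (a `#` header line is
#' skipped), the dialect produced by WFDB's `rdann` after dropping the time
#' column.
#'
#' @param path File path.
#' @param record_id Record identifier to attach.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, record_id = sub("\\..*$", "", basename(path))) {
  if (!file.exists(path)) stopf("format error: annotation file '%s' not found", path)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("sample", "symbol"),
                          colClasses = c("integer", "character"))
  annotation_set(record_id, df$sample, df$symbol)
}

#' Default mapping from MIT-BIH rhythm annotation symbols to rhythm classes
#'
#' Users may extend or replace this table; unknown symbols encountered during
#' labelling are reported in a warning.
#'
#' @return A data.frame with columns `symbol` and `class`.
#' @export
default_symbol_map <- function() {
  data.frame(
    symbol = c("(N", "(NSR", "N", "(VT", "(VFL", "(VF", "(VFIB", "(VFL/VF"),
    class  = c("NSR", "NSR", "NSR", "VT", "VFL", "VFIB", "VFIB", "VFL"),
    stringsAsFactors = FALSE
  )
}

#' Assign one rhythm label per signal segment
#'
#' Splits the record into consecutive `segment_length`-sample windows
#' (dropping any short tail) and labels each. Policy `"record"` assigns the
#' record's own rhythm class (its `rhythm_class` attribute) to every segment;
#' policy `"majority"` maps annotation symbols to classes via `symbol_map`
#' and assigns each window the class covering the most samples in it.
#' Samples under unknown symbols are listed in a warning and count toward no
#' class; a window with no classified samples gets `NA` (to be dropped by the
#' caller).
#'
#' @param record An [ecg_record()].
#' @param annotations An [annotation_set()] (required for `"majority"`).
#' @param segment_length Samples per segment (default 1024).
#' @param policy `"record"` or `"majority"`.
#' @param symbol_map Symbol-to-class table, as [default_symbol_map()].
#'
#' @return Factor of length `floor(n / segment_length)` over
#'   [rhythm_classes()], possibly with `NA`s under `"majority"`.
#' @export
assign_segment_labels <- function(record, annotations = NULL,
                                  segment_length = 1024L,
                                  policy = c("record", "majority"),
                                  symbol_map = default_symbol_map()) {
  policy <- match.arg(policy)
  if (segment_length <= 0) stopf("segment_length must be positive")
  n <- length(record$signals[[1]])
  k <- n %/% segment_length
  if (policy == "record") {
    cls <- attr(record, "rhythm_class")
    if (is.null(cls)) {
      stopf("policy 'record' needs a rhythm_class attribute on the record")
    }
    return(as_rhythm_class(rep(cls, k)))
  }
  if (is.null(annotations)) stopf("policy 'majority' requires annotations")
  ev <- annotations$events
  if (any(ev$sample >= n)) stopf("annotation index beyond record length")
  # class of every sample: most recent event at or before it
  idx <- findInterval(seq_len(n) - 1L, ev$sample)
  sym <- ifelse(idx >= 1, ev$symbol[pmax(idx, 1L)], NA_character_)
  cls <- symbol_map$class[match(sym, symbol_map$symbol)]
  unknown <- unique(sym[!is.na(sym) & is.na(cls)])
  if (length(unknown) > 0) {
    warnf("unknown annotation symbol(s): %s; affected samples unclassified",
          paste(unknown, collapse = ", "))
  }
  out <- rep(NA_character_, k)
  for (s in seq_len(k)) {
    win <- cls[((s - 1L) * segment_length + 1L):(s * segment_length)]
    win <- win[!is.na(win)]
    if (length(win) == 0) next
    tab <- table(win)
    best <- names(tab)[tab == max(tab)]
    # tie: earliest class in canonical order
    out[s] <- rhythm_classes()[min(match(best, rhythm_classes()))]
  }
  factor(out, levels = rhythm_classes())
}

# ---------------------------------------------------------------------------
# Image-dataset persistence: one lossless grayscale PNG per binary image
# (pixel 255 <-> 1) plus a CSV manifest.
# ---------------------------------------------------------------------------

#' Write labelled image sets to a directory
#'
#' One lossless grayscale PNG per binary image (pixel value 255 for 1, 0 for
#' 0) plus a manifest CSV with columns
#' `record_id,segment_index,label,filename`. [read_image_dataset()] is the
#' exact inverse.
#'
#' @param sets A list of labelled image sets as produced by
#'   [transform_record()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_image_dataset <- function(sets, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (set in sets) {
    stopifnot(inherits(set, "labeled_image_set"))
    for (i in seq_along(set$images)) {
      fn <- sprintf("%s_seg%04d.png", set$source_record, set$segment_indices[i])
      png::writePNG(set$images[[i]]$pixels, file.path(out_dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = set$source_record,
        segment_index = set$segment_indices[i],
        label = as.character(set$labels[i]),
        filename = fn, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), segment_index = integer(),
               label = character(), filename = character())
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a labelled image dataset back from a directory
#'
#' @param dir Directory written by [write_image_dataset()].
#' @return A list of labelled image sets, one per record, in manifest order.
#' @export
read_image_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stopf("integrity error: no manifest.csv in '%s'", dir)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) return(list())
  missing <- !file.exists(file.path(dir, manifest$filename))
  if (any(missing)) {
    stopf("integrity error: manifest references missing file(s): %s",
          paste(manifest$filename[missing], collapse = ", "))
  }
  out <- list()
  for (rid in unique(manifest$record_id)) {
    sub <- manifest[manifest$record_id == rid, , drop = FALSE]
    images <- lapply(sub$filename, function(fn) {
      px <- png::readPNG(file.path(dir, fn))
      if (length(dim(px)) == 3) px <- px[, , 1]
      binary_image(round(px))
    })
    out[[length(out) + 1L]] <- labeled_image_set(
      images = images,
      labels = as_rhythm_class(sub$label),
      source_record = rid,
      segment_indices = sub$segment_index)
  }
  out
}
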