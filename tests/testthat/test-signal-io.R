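# WFDB round trips, annotation-driven labels, image-dataset persistence.

test_that("writer/reader round-trip a synthetic record sample-exactly", {
  dir <- withr::local_tempdir()
  rec <- tiny_record("VT", n = 1500, seed = 31L)
  hea <- write_wfdb(rec, dir, gain = 1000)
  back <- read_wfdb(hea)
  expect_equal(back$record_id, rec$record_id)
  expect_equal(length(back$signals), 2)
  expect_equal(back$lead_names, rec$lead_names)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  # digitisation at gain 1000 quantises to 0.001; round-trip to that grid
  for (ld in 1:2) {
    digital <- pmin(pmax(round(rec$signals[[ld]] * 1000), -32768), 32767)
    expect_equal(back$signals[[ld]], digital / 1000)
  }
})

test_that("truncated signal files raise a format error naming the file", {
  dir <- withr::local_tempdir()
  rec <- tiny_record("NSR", n = 1200, seed = 8L)
  hea <- write_wfdb(rec, dir)
  dat <- file.path(dir, paste0(rec$record_id, ".dat"))
  bytes <- readBin(dat, "raw", n = file.size(dat))
  writeBin(bytes[1:100], dat)
  expect_error(read_wfdb(hea), "format error.*\\.dat")
  file.remove(dat)
  expect_error(read_wfdb(hea), "format error.*not found")
  expect_error(read_wfdb(file.path(dir, "nonexistent.hea")), "format error")
})

test_that("format 212 packed samples decode with gain and baseline applied", {
  dir <- withr::local_tempdir()
  digital <- c(-5L, 100L, 2047L, -2048L)
  # hand-pack 12-bit two's complement pairs into 3-byte groups
  enc <- function(a, b) {
    a12 <- a %% 4096L; b12 <- b %% 4096L
    as.raw(c(a12 %% 256L, (a12 %/% 256L) + 16L * (b12 %/% 256L), b12 %% 256L))
  }
  bytes <- c(enc(digital[1], digital[2]), enc(digital[3], digital[4]))
  writeBin(bytes, file.path(dir, "r212.dat"))
  writeLines(c("r212 1 360 4",
               "r212.dat 212 100(10)/mV 12 0 -5 0 0 MLII"),
             file.path(dir, "r212.hea"))
  rec <- read_wfdb(file.path(dir, "r212.hea"))
  expect_equal(rec$signals[[1]], (digital - 10) / 100)
  expect_equal(rec$lead_names, "MLII")
})

test_that("record policy labels every segment with the record class", {
  rec <- tiny_record("VFIB", n = 5000, seed = 3L)
  labs <- assign_segment_labels(rec, segment_length = 1024)
  expect_length(labs, 4)  # floor(5000 / 1024)
  expect_true(all(labs == "VFIB"))
})

test_that("majority policy follows annotation coverage within each window", {
  rec <- ecg_record("ann", list(rnorm(2048)), 360)
  # class switch exactly at the segment boundary
  ann <- annotation_set("ann", c(0, 1024), c("(N", "(VT"))
  labs <- assign_segment_labels(rec, ann, 1024, policy = "majority")
  expect_equal(as.character(labs), c("NSR", "VT"))
  # 600 samples of VT vs 424 of NSR inside one window -> VT
  rec1 <- ecg_record("ann1", list(rnorm(1024)), 360)
  ann1 <- annotation_set("ann1", c(0, 600), c("(VT", "(N"))
  expect_equal(as.character(
    assign_segment_labels(rec1, ann1, 1024, policy = "majority")), "VT")
})

test_that("unknown annotation symbols warn and leave segments unlabelled", {
  rec <- ecg_record("odd", list(rnorm(2048)), 360)
  ann <- annotation_set("odd", c(0, 1024), c("(ZZZ", "(N"))
  expect_warning(
    labs <- assign_segment_labels(rec, ann, 1024, policy = "majority"),
    "unknown annotation symbol")
  expect_true(is.na(labs[1]))
  expect_equal(as.character(labs[2]), "NSR")
})

test_that("label count equals floor(record length / segment length)", {
  set.seed(77)
  for (i in 1:6) {
    n <- sample(100:6000, 1)
    L <- sample(c(64, 256, 1024), 1)
    rec <- ecg_record("p", list(rnorm(n)), 250)
    attr(rec, "rhythm_class") <- "NSR"
    expect_length(assign_segment_labels(rec, segment_length = L), n %/% L)
  }
})

test_that("annotation text files read back as annotation sets", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# sample symbol", "0 (N", "512 (VF"), path)
  ann <- read_annotations(path, "rec9")
  expect_equal(ann$events$sample, c(0L, 512L))
  expect_equal(ann$events$symbol, c("(N", "(VF"))
  expect_error(annotation_set("x", c(10, 5), c("a", "b")), "non-decreasing")
})

test_that("image dataset write/read is the identity, in order", {
  dir <- withr::local_tempdir()
  sets <- list(
    transform_record(tiny_record("NSR", 2048, seed = 1L)),
    transform_record(tiny_record("VFL", 3072, seed = 2L))
  )
  write_image_dataset(sets, dir)
  back <- read_image_dataset(dir)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$source_record, sets[[i]]$source_record)
    expect_equal(as.character(back[[i]]$labels), as.character(sets[[i]]$labels))
    expect_equal(back[[i]]$segment_indices, sets[[i]]$segment_indices)
    for (j in seq_along(sets[[i]]$images)) {
      expect_identical(back[[i]]$images[[j]]$pixels,
                       sets[[i]]$images[[j]]$pixels)
    }
  }
})

test_that("empty image-set lists write an empty manifest without error", {
  dir <- withr::local_tempdir()
  write_image_dataset(list(), dir)
  expect_length(read_image_dataset(dir), 0)
})

test_that("a manifest referencing a missing file is an integrity error", {
  dir <- withr::local_tempdir()
  write_image_dataset(list(transform_record(tiny_record("VT", 2048))), dir)
  pngs <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  file.remove(pngs[1])
  expect_error(read_image_dataset(dir), "integrity error")
  expect_error(read_image_dataset(withr::local_tempdir()), "integrity error")
})
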