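# Histogram entropy scoring and fraction-based selection.

test_that("entropy matches a brute-force histogram oracle", {
  set.seed(55)
  for (i in 1:10) {
    x <- rnorm(200)
    n_bins <- sample(c(8, 64, 256), 1)
    h <- feature_entropy(matrix(x, ncol = 1), n_bins)
    expect_equal(as.numeric(h), oracle_entropy(x, n_bins), tolerance = 1e-12)
  }
})

test_that("entropy hits its analytic landmarks", {
  # constant column: one occupied bin, zero bits
  expect_equal(as.numeric(feature_entropy(matrix(3.3, 10, 1))), 0)
  # half the values in each of two occupied bins: exactly one bit
  twobin <- matrix(c(rep(0, 8), rep(1, 8)), ncol = 1)
  expect_equal(as.numeric(feature_entropy(twobin, n_bins = 2)), 1)
  # 256 values uniformly filling 256 bins: exactly eight bits
  u <- matrix(0:255, ncol = 1)
  expect_equal(as.numeric(feature_entropy(u, n_bins = 256)), 8)
  expect_equal(oracle_entropy(0:255 + 0.0, 256), 8)  # oracle agrees
})

test_that("entropy is bounded by log2(n_bins) and row-permutation invariant", {
  set.seed(66)
  for (i in 1:10) {
    m <- matrix(rnorm(300), ncol = 3)
    n_bins <- sample(c(4, 16, 256), 1)
    h <- feature_entropy(m, n_bins)
    expect_true(all(h >= 0 & h <= log2(n_bins) + 1e-12))
    perm <- sample(nrow(m))
    expect_equal(as.numeric(feature_entropy(m[perm, ], n_bins)),
                 as.numeric(h))
  }
  expect_error(feature_entropy(matrix(1, 1, 3)), "insufficient data")
  expect_error(feature_entropy(matrix(c(1, NA), 2, 1)), "data error")
  expect_error(feature_entropy(matrix(1:4, 2, 2), n_bins = 1), "n_bins")
})

test_that("selection arithmetic reproduces the fused-width fractions", {
  d <- 10240L
  ent <- structure(seq_len(d) / d, class = "entropy_vector", n_bins = 256L)
  feats <- matrix(rnorm(2 * d), nrow = 2)
  s50 <- select_by_entropy(feats, ent, fraction = 0.5)
  expect_length(s50$selected_indices, 5120)
  s25 <- select_by_entropy(feats, ent, fraction = 0.25)
  expect_length(s25$selected_indices, 2560)
  expect_equal(ncol(s50$reduced), 5120)
})

test_that("selection follows the sort order with index tie-breaks", {
  # spec-style hand case: entropies (3, 1, 2) bits, keep 2/3 ascending
  feats <- matrix(rnorm(9), nrow = 3)
  ent <- structure(c(3, 1, 2), class = "entropy_vector", n_bins = 4L)
  sel <- select_by_entropy(feats, ent, fraction = 2 / 3)
  expect_equal(sel$selected_indices, c(2L, 3L))
  # exhaustive sort oracle on small random cases, both directions, with ties
  set.seed(88)
  for (i in 1:20) {
    d <- sample(2:10, 1)
    e <- sample(c(0, 0.5, 1, 2), d, replace = TRUE)
    ent <- structure(e, class = "entropy_vector", n_bins = 4L)
    f <- matrix(rnorm(2 * d), nrow = 2)
    frac <- runif(1, 0.05, 1)
    k <- max(1, sign(frac * d) * floor(abs(frac * d) + 0.5))
    for (ord in c("ascending", "descending")) {
      key <- if (ord == "ascending") e else -e
      oracle <- order(key, seq_len(d))[seq_len(k)]  # stable exhaustive sort
      sel <- select_by_entropy(f, ent, fraction = frac, order = ord)
      expect_equal(sel$selected_indices, oracle)
      # rank invariant: every kept entropy on the kept side of every dropped
      dropped <- setdiff(seq_len(d), sel$selected_indices)
      if (length(dropped)) {
        if (ord == "ascending") {
          expect_true(max(e[sel$selected_indices]) <= min(e[dropped]))
        } else {
          expect_true(min(e[sel$selected_indices]) >= max(e[dropped]))
        }
      }
    }
  }
})

test_that("selection is idempotent and fraction 1 keeps everything", {
  set.seed(9)
  f <- matrix(rnorm(40 * 12), nrow = 40)
  all_sel <- select_by_entropy(f, fraction = 1)
  expect_setequal(all_sel$selected_indices, 1:12)
  half_direct <- select_by_entropy(f, fraction = 0.5)
  half_after <- select_by_entropy(all_sel$reduced, fraction = 0.5)
  # composing through the full selection picks the same features
  expect_equal(sort(all_sel$selected_indices[half_after$selected_indices]),
               sort(half_direct$selected_indices))
  expect_error(select_by_entropy(f, fraction = 0), "config error")
  expect_error(select_by_entropy(f, fraction = 1.2), "config error")
})

test_that("selection results round-trip through JSON", {
  dir <- withr::local_tempdir()
  f <- matrix(rnorm(60), nrow = 10)
  sel <- select_by_entropy(f, fraction = 0.5, n_bins = 8)
  path <- file.path(dir, "sel.json")
  write_selection_json(sel, path)
  back <- read_selection_json(path)
  expect_equal(back$selected_indices, sel$selected_indices)
  expect_equal(back$fraction, 0.5)
  expect_equal(back$n_bins, 8)
  expect_equal(back$entropy, as.numeric(sel$entropy))
})
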