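# Shared tiny fixtures, built in code at test time.

# A short record per class, cheap enough for any test.
tiny_record <- function(cls = "NSR", n = 2048L, seed = 11L, noise_sd = 0.05) {
  generate_record(simulation_config(cls, n_samples = n, seed = seed,
                                    noise_sd = noise_sd))
}

# A handful of distinct binary images.
tiny_images <- function(n = 5L, side = 32L, seed = 99L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    binary_image(matrix(rbinom(side * side, 1, 0.3), side, side))
  })
}

# Independent brute-force histogram entropy (the oracle for feature_entropy).
oracle_entropy <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  cnt <- table(cut(x, breaks = edges, include.lowest = TRUE))
  p <- as.numeric(cnt) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Count upward crossings of a fixed threshold per second (beat-rate oracle).
crossing_rate <- function(x, fs, thr = 0.5 * max(x)) {
  above <- x > thr
  sum(diff(above) == 1) / (length(x) / fs)
}
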