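# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops and textbook formulas.

# count-and-sum Shannon entropy (bits) of a probability vector
oracle_entropy_probs <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# plug-in entropy (bits) of a symbol sequence by explicit counting
oracle_entropy_sequence <- function(codes) {
  n <- length(codes)
  h <- 0
  for (u in unique(codes)) {
    cnt <- 0
    for (c in codes) if (c == u) cnt <- cnt + 1
    p <- cnt / n
    h <- h - p * log2(p)
  }
  h
}

# conditional entropy H(next | current) by explicit transition counting
oracle_conditional_entropy <- function(codes) {
  n <- length(codes) - 1
  h <- 0
  for (u in unique(codes[seq_len(n)])) {
    nxt <- codes[which(codes[seq_len(n)] == u) + 1]
    p_u <- length(nxt) / n
    h <- h + p_u * oracle_entropy_sequence(nxt)
  }
  h
}

# textbook two-pass sample variance
oracle_variance <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# brute-force Pearson correlation
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# linear-scan histogram counts for equal-width edges (right-open bins,
# last bin closed)
oracle_histogram <- function(vals, edges) {
  n_bins <- length(edges) - 1
  counts <- integer(n_bins)
  for (v in vals) {
    for (b in seq_len(n_bins)) {
      in_bin <- if (b < n_bins) v >= edges[b] && v < edges[b + 1]
                else v >= edges[b] && v <= edges[b + 1]
      if (in_bin) { counts[b] <- counts[b] + 1; break }
    }
  }
  counts
}

# random probability vector over k cells (some zeros allowed)
random_probs <- function(k, zero_frac = 0.3) {
  w <- stats::rexp(k)
  w[stats::runif(k) < zero_frac] <- 0
  if (sum(w) == 0) w[1] <- 1
  w / sum(w)
}

# a minimal motif_sequence object for direct entropy/repertoire tests
fake_motif_sequence <- function(codes, k = 4L) {
  structure(list(codes = as.integer(codes),
                 starts = seq_along(codes) - 1L, k = k,
                 node_names = paste0("r", seq_len(k)), window_len = 20L,
                 step = 1L, threshold = 0.5, use_absolute = FALSE,
                 n_dropped = 0L),
            class = "motif_sequence")
}

# small fast generator config for tests
test_config <- function(...) {
  generator_config(voxels_per_network = 8L, ...)
}
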