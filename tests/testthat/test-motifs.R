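random_region_ts <- function(k = 4, n_t = 120, seed = 1) {
  set.seed(seed)
  region_ts(matrix(rnorm(k * n_t), nrow = k), paste0("r", seq_len(k)), 3)
}

test_that("window arithmetic and correlations match brute force", {
  rs <- random_region_ts(n_t = 100, seed = 51)
  wc <- windowed_connectivity(rs, window_len = 30, step = 10)
  expect_length(wc$matrices, 8)           # floor((100 - 30) / 10) + 1
  expect_equal(wc$starts, seq(0, 70, by = 10))
  for (i in seq_along(wc$starts)) {
    idx <- (wc$starts[i] + 1):(wc$starts[i] + 30)
    for (a in 1:3) for (b in (a + 1):4)
      expect_equal(wc$matrices[[i]][a, b],
                   oracle_pearson(rs$data[a, idx], rs$data[b, idx]),
                   tolerance = 1e-12)
    expect_equal(diag(wc$matrices[[i]]), rep(1, 4), ignore_attr = TRUE)
  }
  # two regions, identical series: off-diagonal exactly 1
  dup <- region_ts(rbind(rs$data[1, ], rs$data[1, ]), c("a", "b"), 3)
  expect_equal(windowed_connectivity(dup, 30, 10)$matrices[[1]][1, 2], 1)
  expect_error(windowed_connectivity(rs, window_len = 200), "shorter")
})

test_that("windows containing a constant region are dropped and counted", {
  x <- matrix(rnorm(4 * 60), nrow = 4)
  x[2, 1:25] <- 5                          # constant through early windows
  rs <- region_ts(x, paste0("r", 1:4), 3)
  expect_message(wc <- windowed_connectivity(rs, window_len = 20, step = 5),
                 "dropped")
  expect_gt(wc$n_dropped, 0)
  expect_equal(length(wc$matrices) + wc$n_dropped, 9)
})

test_that("thresholding follows the sign convention", {
  m9 <- matrix(0.9, 4, 4); diag(m9) <- 1
  expect_equal(binarize(m9, 0.5), {
    a <- matrix(1L, 4, 4); diag(a) <- 0L; a
  })
  m1 <- matrix(0.1, 4, 4); diag(m1) <- 1
  expect_true(all(binarize(m1, 0.5) == 0))
  mn <- matrix(-0.8, 2, 2); diag(mn) <- 1
  expect_equal(binarize(mn, 0.5)[1, 2], 0L)
  expect_equal(binarize(mn, 0.5, use_absolute = TRUE)[1, 2], 1L)
  asym <- matrix(c(1, 0.2, 0.8, 1), 2, 2)
  expect_error(binarize(asym, 0.5), "symmetric")
  expect_error(binarize(m9, 1.2), "threshold")
})

test_that("motif codes follow the lexicographic bit convention and are
           bijective", {
  empty <- matrix(0L, 4, 4)
  expect_equal(encode_motif(empty), 0L)
  full <- matrix(1L, 4, 4); diag(full) <- 0L
  expect_equal(encode_motif(full), 63L)
  e01 <- matrix(0L, 4, 4); e01[1, 2] <- e01[2, 1] <- 1L
  expect_equal(encode_motif(e01), 1L)
  e23 <- matrix(0L, 4, 4); e23[3, 4] <- e23[4, 3] <- 1L
  expect_equal(encode_motif(e23), 32L)    # last pair = highest bit
  bad <- empty; diag(bad) <- 1L
  expect_error(encode_motif(bad), "diagonal")
  # exhaustive bijection over all 64 four-node patterns
  seen <- integer(0)
  for (code in 0:63) {
    adj <- decode_motif(code, 4)
    expect_true(all(adj == t(adj)) && all(diag(adj) == 0))
    expect_equal(encode_motif(adj), code)
    seen <- c(seen, code)
  }
  expect_equal(sort(unique(seen)), 0:63)
})

test_that("motif-space size is 2^(k(k-1)/2)", {
  expect_identical(count_possible_motifs(2), 2)
  expect_identical(count_possible_motifs(4), 64)
  # independent enumeration for k = 5: all binary labelings of 10 pairs
  grid <- expand.grid(rep(list(0:1), 5 * 4 / 2))
  expect_identical(count_possible_motifs(5), as.numeric(nrow(grid)))
  expect_error(count_possible_motifs(1), "k")
})

test_that("repertoire counts distinct motifs and condition exclusives", {
  r0 <- motif_repertoire(fake_motif_sequence(c(0, 0, 0)))
  expect_equal(r0$n_distinct, 1)
  expect_equal(r0$frequency$count, 3)
  self <- motif_repertoire(fake_motif_sequence(c(0, 0, 0)),
                           fake_motif_sequence(c(0, 0, 0)))
  expect_length(self$exclusive, 0)
  cmp <- motif_repertoire(fake_motif_sequence(c(1, 2, 3)),
                          fake_motif_sequence(c(1, 2)))
  expect_equal(cmp$exclusive, 3L)
  expect_error(motif_repertoire(fake_motif_sequence(c(1, 2), k = 4),
                                fake_motif_sequence(c(1, 2), k = 3)),
               "node counts")
})

test_that("motif entropy matches anchors and the counting oracle", {
  expect_equal(motif_entropy(fake_motif_sequence(rep(7, 20)), 0), 0)
  expect_equal(motif_entropy(fake_motif_sequence(rep(7, 20)), 1), 0)
  expect_equal(motif_entropy(fake_motif_sequence(rep(0:63, 4)), 0), 6)
  alt <- fake_motif_sequence(rep(c(3, 9), 30))
  expect_equal(motif_entropy(alt, 0), 1)
  expect_equal(motif_entropy(alt, 1), 0)  # deterministic alternation
  expect_error(motif_entropy(alt, 2), "order")
  set.seed(52)
  for (rep in 1:25) {
    codes <- sample(0:63, sample(10:200, 1), replace = TRUE)
    sq <- fake_motif_sequence(codes)
    expect_equal(motif_entropy(sq, 0), oracle_entropy_sequence(codes),
                 tolerance = 1e-12)
    expect_equal(motif_entropy(sq, 1), oracle_conditional_entropy(codes),
                 tolerance = 1e-12)
  }
})

test_that("motif entropy is invariant under relabeling of the codes", {
  set.seed(53)
  for (rep in 1:20) {
    codes <- sample(0:63, 150, replace = TRUE)
    perm <- sample(0:63)
    relabeled <- perm[codes + 1]
    expect_equal(motif_entropy(fake_motif_sequence(codes), 0),
                 motif_entropy(fake_motif_sequence(relabeled), 0),
                 tolerance = 1e-12)
    expect_equal(motif_entropy(fake_motif_sequence(codes), 1),
                 motif_entropy(fake_motif_sequence(relabeled), 1),
                 tolerance = 1e-12)
  }
})

test_that("the full motif pipeline runs on generated ROI data", {
  r <- generate_roi_dataset(test_config(seed = 54,
                                        condition = "drug_like",
                                        n_regimes = 8, switch_rate = 0.2))
  sq <- suppressMessages(motif_sequence(r))
  expect_true(all(sq$codes >= 0 & sq$codes <= 63))
  expect_equal(length(sq$codes) + sq$n_dropped, 240 - 20 + 1)
  expect_lte(motif_entropy(sq, 1), motif_entropy(sq, 0) + 1e-12)
})
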