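# Time-resolved connectivity motifs over a small ROI set: sliding-window
# Pearson correlation, thresholding to a binary graph, bijective encoding of
# the graph as an integer motif code, repertoire and sequence entropy.
#
# Bit convention: for k nodes, the node pairs are ordered lexicographically
# (0,1), (0,2), ..., (0,k-1), (1,2), ..., (k-2,k-1) and pair number b
# (0-based) contributes 2^b when its edge is present. For k = 4 the codes
# run 0..63: the empty graph is 0, the complete graph 63, and the single
# edge (0,1) is 1.

#' Sliding-window connectivity matrices
#'
#' For each window `[t, t + window_len)` advancing by `step` inside the
#' segment, the symmetric matrix of pairwise Pearson correlations between
#' regions (diagonal 1). The number of windows is
#' `floor((segment_len - window_len) / step) + 1`. A window in which any
#' region is constant has undefined correlations and is dropped; the count
#' of dropped windows is returned.
#'
#' @param series a [region_ts()].
#' @param window_len window length in timepoints (>= 3; default 20,
#'   i.e. 60 s at a 3-s sampling interval).
#' @param step window increment in timepoints (default 1).
#' @param seg optional [segment()]; default the full scan.
#' @return list with `matrices` (list of k x k correlation matrices),
#'   `starts` (0-based window starts), `n_dropped`.
#' @export
windowed_connectivity <- function(series, window_len = 20L, step = 1L,
                                  seg = NULL) {
  stopifnot(inherits(series, "region_ts"))
  window_len <- stopifnot_count(window_len, "window_len", min = 3L)
  step <- stopifnot_count(step, "step", min = 1L)
  n <- ncol(series$data)
  if (is.null(seg)) seg <- segment(0L, n)
  seg_len <- segment_length(seg)
  if (seg_len < window_len)
    stop("segment (", seg_len, " timepoints) shorter than window_len (",
         window_len, ")")
  starts <- seq.int(seg[1L], seg[2L] - window_len, by = step)
  mats <- vector("list", length(starts))
  ok <- logical(length(starts))
  for (i in seq_along(starts)) {
    w <- t(series$data[, (starts[i] + 1L):(starts[i] + window_len),
                       drop = FALSE])
    if (any(apply(w, 2L, stats::sd) == 0)) next   # constant region: drop
    mats[[i]] <- stats::cor(w)
    ok[i] <- TRUE
  }
  if (!all(ok))
    message(sum(!ok), " window(s) dropped (constant region)")
  list(matrices = mats[ok], starts = starts[ok], n_dropped = sum(!ok))
}

#' Threshold a correlation matrix into a binary adjacency pattern
#'
#' Edge `(i, j)` is present iff `c_ij > threshold` (or `|c_ij| > threshold`
#' with `use_absolute`). The diagonal is ignored and returned as zero.
#'
#' @param corr_matrix symmetric correlation matrix.
#' @param threshold connection-strength threshold in (-1, 1); default 0.5.
#' @param use_absolute threshold the absolute correlation instead of the
#'   signed value (default `FALSE`).
#' @param tol symmetry tolerance.
#' @return k x k binary symmetric matrix with zero diagonal.
#' @export
binarize <- function(corr_matrix, threshold = 0.5, use_absolute = FALSE,
                     tol = 1e-8) {
  corr_matrix <- as.matrix(corr_matrix)
  if (nrow(corr_matrix) != ncol(corr_matrix) ||
      any(abs(corr_matrix - t(corr_matrix)) > tol))
    stop("correlation matrix must be symmetric")
  if (threshold <= -1 || threshold >= 1)
    stop("threshold must lie in (-1, 1)")
  v <- if (use_absolute) abs(corr_matrix) else corr_matrix
  adj <- (v > threshold) * 1L
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  adj
}

#' Encode a binary adjacency pattern as a motif code
#'
#' Bijective with [decode_motif()] under the lexicographic pair-bit
#' convention described above; for 4 nodes the 2^6 = 64 possible codes are
#' 0 (empty graph) through 63 (complete graph).
#'
#' @param adjacency k x k binary symmetric matrix with zero diagonal.
#' @return integer motif code in `[0, 2^(k(k-1)/2) - 1]`.
#' @export
encode_motif <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  k <- nrow(adjacency)
  if (k != ncol(adjacency)) stop("adjacency must be square")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!all(adjacency %in% c(0L, 1L)) ||
      any(adjacency != t(adjacency)))
    stop("adjacency must be binary and symmetric")
  bit <- 0L; code <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (adjacency[i, j] == 1L) code <- code + 2^bit
      bit <- bit + 1L
    }
  }
  as.integer(code)
}

#' @rdname encode_motif
#' @param code integer motif code.
#' @param k node count.
#' @export
decode_motif <- function(code, k) {
  k <- stopifnot_count(k, "k", min = 2L)
  n_codes <- 2^(k * (k - 1L) / 2)
  if (code < 0 || code >= n_codes || code != round(code))
    stop("code must be an integer in [0, ", n_codes - 1, "]")
  adj <- matrix(0L, k, k)
  bit <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (bitwAnd(as.integer(code), bitwShiftL(1L, bit)) != 0L)
        adj[i, j] <- adj[j, i] <- 1L
      bit <- bit + 1L
    }
  }
  adj
}

#' Number of possible connectivity motifs for k labeled nodes
#'
#' `2^(k(k-1)/2)`: every subset of the `k(k-1)/2` undirected node pairs is a
#' distinct motif (the empty graph counts). Four nodes give 64.
#'
#' @param k node count (>= 2).
#' @return the motif-space size.
#' @export
count_possible_motifs <- function(k) {
  k <- stopifnot_count(k, "k", min = 2L)
  2^(k * (k - 1) / 2)
}

#' Motif sequence of a region time series
#'
#' Full motif pipeline: sliding-window correlations, thresholding, and
#' encoding each window's binary graph as a motif code.
#'
#' @inheritParams windowed_connectivity
#' @inheritParams binarize
#' @return object of class `motif_sequence`: `codes` (integer vector, one
#'   per retained window), `starts`, `k`, `node_names`, `window_len`,
#'   `step`, `threshold`, `use_absolute`, `n_dropped`.
#' @export
motif_sequence <- function(series, window_len = 20L, step = 1L,
                           threshold = 0.5, use_absolute = FALSE,
                           seg = NULL) {
  wc <- windowed_connectivity(series, window_len, step, seg)
  codes <- vapply(wc$matrices,
                  function(m) encode_motif(binarize(m, threshold,
                                                    use_absolute)),
                  integer(1))
  if (length(codes) == 0L)
    stop("no usable windows (all dropped)")
  structure(list(codes = codes, starts = wc$starts,
                 k = nrow(series$data), node_names = series$region_names,
                 window_len = window_len, step = step,
                 threshold = threshold, use_absolute = use_absolute,
                 n_dropped = wc$n_dropped),
            class = "motif_sequence")
}

#' @export
print.motif_sequence <- function(x, ...) {
  cat("<motif_sequence> ", length(x$codes), " windows (len ", x$window_len,
      ", step ", x$step, "), k = ", x$k, ", threshold ", x$threshold,
      if (x$use_absolute) " (absolute)", ", ",
      length(unique(x$codes)), " distinct motifs\n", sep = "")
  invisible(x)
}

#' Motif repertoire of a sequence
#'
#' Distinct motif count, per-motif occurrence table, and — when a baseline
#' sequence is given — the motifs exclusive to the sequence (present in it,
#' absent from baseline).
#'
#' @param seq a `motif_sequence`.
#' @param baseline optional comparison `motif_sequence` with the same node
#'   count and window parameters.
#' @return list with `n_distinct`, `frequency` (data.frame of `code`,
#'   `count`), `exclusive` (integer codes; `NULL` without a baseline).
#' @export
motif_repertoire <- function(seq, baseline = NULL) {
  stopifnot(inherits(seq, "motif_sequence"))
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "motif_sequence"))
    if (baseline$k != seq$k)
      stop("sequences have different node counts (", seq$k, " vs ",
           baseline$k, ")")
    if (baseline$window_len != seq$window_len ||
        baseline$step != seq$step ||
        baseline$threshold != seq$threshold)
      stop("sequences were built with different window parameters; not comparable")
  }
  tab <- table(seq$codes)
  freq <- data.frame(code = as.integer(names(tab)),
                     count = as.integer(tab))
  freq <- freq[order(-freq$count, freq$code), , drop = FALSE]
  rownames(freq) <- NULL
  list(n_distinct = nrow(freq), frequency = freq,
       exclusive = if (is.null(baseline)) NULL
                   else sort(setdiff(seq$codes, baseline$codes)))
}

#' Entropy of a motif sequence
#'
#' Order 0: plug-in Shannon entropy (bits) of the motif frequency
#' distribution — how unpredictable the repertoire is, the same computation
#' one would apply to word frequencies in a passage of text. Order 1: the
#' conditional entropy of the next motif given the current one, estimated
#' from transition counts — how unpredictable the sequence dynamics are.
#' Both are bounded by `log2(count_possible_motifs(k))` (6 bits for 4
#' nodes), and conditioning can only reduce entropy, so order 1 <= order 0.
#'
#' @param seq a `motif_sequence` (length >= 2; order 1 needs >= 3).
#' @param order 0 (marginal, default) or 1 (conditional on the previous
#'   motif).
#' @return entropy in bits.
#' @export
motif_entropy <- function(seq, order = 0L) {
  stopifnot(inherits(seq, "motif_sequence"))
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  codes <- seq$codes
  if (length(codes) < 2L) stop("sequence must have length >= 2")
  if (order == 0L) {
    p <- as.numeric(table(codes)) / length(codes)
    return(-sum(p * log2(p)))
  }
  if (length(codes) < 3L) stop("order-1 entropy needs length >= 3")
  cur <- codes[-length(codes)]
  nxt <- codes[-1L]
  n <- length(cur)
  h <- 0
  for (c0 in unique(cur)) {
    sel <- cur == c0
    p_c <- sum(sel) / n
    p_next <- as.numeric(table(nxt[sel])) / sum(sel)
    h <- h + p_c * (-sum(p_next * log2(p_next)))
  }
  h
}
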