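# Discretization of synchrony traces and Shannon entropy of the resulting
# distributions. Bins are equal-width; by default the bin edges span the
# pooled range of the pre and post segments of a trace, so the two
# distributions share a support and their entropy difference is meaningful.

#' Discretize a synchrony trace into an equal-width binned distribution
#'
#' Every timepoint of the segment falls into exactly one bin; bins are
#' right-open except the last, which is closed. Probabilities are
#' counts / n_samples. Edge placement is controlled by `edges_strategy`:
#' \describe{
#'   \item{`"pooled"`}{equal-width bins spanning the combined range of the
#'     values in `seg` and in `pool_with` (when given) — the default, so a
#'     pre and a post distribution built with the same `pool_with` pairing
#'     share identical edges.}
#'   \item{`"fixed"`}{equal-width bins over the user-supplied `range`.}
#'   \item{`"centered"`}{equal-width bins on the absolute deviation of each
#'     value from the pooled mean, from 0 to the maximum absolute
#'     deviation — the "distance from the mean" reading of binning.}
#' }
#' A degenerate range (all values identical) yields a single occupied bin
#' with a warning rather than an error.
#'
#' @param trace a `synchrony_trace`, or a plain numeric vector (then `seg`
#'   indexes it directly).
#' @param seg a [segment()] selecting the timepoints to bin.
#' @param n_bins number of bins (>= 2; default 10).
#' @param edges_strategy `"pooled"`, `"fixed"` or `"centered"`.
#' @param pool_with optional second [segment()] pooled with `seg` when
#'   placing edges (typically: the other of the pre/post pair).
#' @param range numeric length-2, required for `"fixed"`.
#' @return object of class `binned_distribution`: `bin_edges` (length
#'   `n_bins + 1`), `probabilities`, `counts`, `n_samples`.
#' @export
discretize <- function(trace, seg, n_bins = 10L,
                       edges_strategy = c("pooled", "fixed", "centered"),
                       pool_with = NULL, range = NULL) {
  edges_strategy <- match.arg(edges_strategy)
  n_bins <- stopifnot_count(n_bins, "n_bins", min = 2L)
  vals <- trace_values(trace, seg)
  if (length(vals) < n_bins)
    stop("segment has ", length(vals), " timepoints; need at least n_bins (",
         n_bins, ")")
  ref <- if (!is.null(pool_with)) c(vals, trace_values(trace, pool_with))
         else vals
  if (edges_strategy == "centered") {
    mu <- mean(ref)
    vals <- abs(vals - mu)
    ref <- abs(ref - mu)
  }
  lims <- switch(edges_strategy,
    pooled = , centered = base::range(ref),
    fixed = {
      if (is.null(range) || length(range) != 2L)
        stop("edges_strategy 'fixed' needs a length-2 'range'")
      sort(as.numeric(range))
    })
  if (edges_strategy == "centered") lims[1L] <- 0
  if (lims[1L] == lims[2L]) {
    warning("degenerate value range (all values equal); ",
            "returning a single-occupied-bin distribution")
    lims <- lims + c(-0.5, 0.5)
  }
  edges <- seq(lims[1L], lims[2L], length.out = n_bins + 1L)
  bins <- findInterval(vals, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  counts <- tabulate(bins, nbins = n_bins)
  structure(list(bin_edges = edges, probabilities = counts / length(vals),
                 counts = counts, n_samples = length(vals)),
            class = "binned_distribution")
}

trace_values <- function(trace, seg) {
  if (inherits(trace, "synchrony_trace")) {
    cl <- segment_intersect(seg, trace$valid_range)
    if (is.null(cl))
      stop("segment does not overlap the trace's valid range")
    trace$values[segment_index(cl, length(trace$values))]
  } else {
    vals <- as.numeric(trace)
    vals[segment_index(seg, length(vals))]
  }
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat("<binned_distribution> ", length(x$probabilities), " bins over [",
      signif(x$bin_edges[1L], 4), ", ",
      signif(x$bin_edges[length(x$bin_edges)], 4), "], n = ", x$n_samples,
      "\n", sep = "")
  invisible(x)
}

#' Shannon entropy of a binned distribution
#'
#' `H = -sum(p * log2(p))` in bits, with the convention `0 * log2(0) = 0`.
#' Bounded by `[0, log2(n_bins)]`. The optional Miller–Madow correction adds
#' `(m - 1) / (2 n ln 2)` (m = occupied bins, n = samples) to offset the
#' negative bias of the plug-in estimator; it is off by default.
#'
#' @param dist a `binned_distribution`, or a bare probability vector.
#' @param correction `"none"` (default) or `"miller_madow"`.
#' @param tol tolerance for the sum-to-one check.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(dist, correction = c("none", "miller_madow"),
                            tol = 1e-8) {
  correction <- match.arg(correction)
  p <- if (inherits(dist, "binned_distribution")) dist$probabilities
       else as.numeric(dist)
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop("probabilities must be non-negative and sum to 1 (sum = ",
         format(sum(p)), ")")
  nz <- p[p > 0]
  h <- -sum(nz * log2(nz))
  if (correction == "miller_madow") {
    if (!inherits(dist, "binned_distribution"))
      stop("Miller-Madow correction needs sample counts; pass a ",
           "binned_distribution")
    h <- h + (length(nz) - 1) / (2 * dist$n_samples * log(2))
  }
  h
}

#' Entropy change between two comparable distributions
#'
#' `H(post) - H(pre)` in bits. The two distributions must have been built
#' with identical bin edges (same support), otherwise the difference is not
#' comparable and an error is raised.
#'
#' @param pre,post `binned_distribution` objects sharing edges.
#' @param tol edge-equality tolerance.
#' @return entropy difference in bits.
#' @export
entropy_change <- function(pre, post, tol = 1e-10) {
  stopifnot(inherits(pre, "binned_distribution"),
            inherits(post, "binned_distribution"))
  if (length(pre$bin_edges) != length(post$bin_edges) ||
      any(abs(pre$bin_edges - post$bin_edges) > tol))
    stop("distributions were built with different bin edges; ",
         "rebuild both with a shared (pooled or fixed) edge set")
  shannon_entropy(post) - shannon_entropy(pre)
}

#' Pre/post synchrony entropy of one network
#'
#' Builds the pre- and post-infusion binned distributions of a synchrony
#' trace on a shared pooled support and returns both entropies and the
#' entropy change.
#'
#' @inheritParams network_metastability
#' @param n_bins number of bins (default 10).
#' @param edges_strategy passed to [discretize()] (`"pooled"` default, or
#'   `"centered"`).
#' @return list with `network_label`, `mode`, `h_pre`, `h_post`, `delta_h`.
#' @export
network_entropy <- function(dataset, network_label,
                            mode = c("amplitude", "phase"),
                            n_bins = 10L,
                            edges_strategy = c("pooled", "centered"),
                            band_low_hz = 0.01, band_high_hz = 0.1) {
  mode <- match.arg(mode)
  edges_strategy <- match.arg(edges_strategy)
  trace <- if (mode == "phase")
    phase_trace(dataset, network_label, band_low_hz, band_high_hz)
  else amplitude_trace(dataset, network_label)
  pre <- segment_intersect(pre_segment(dataset), trace$valid_range)
  post <- segment_intersect(post_segment(dataset), trace$valid_range)
  if (is.null(pre) || is.null(post))
    stop("pre or post segment does not overlap the trace's valid range")
  d_pre <- discretize(trace, pre, n_bins, edges_strategy, pool_with = post)
  d_post <- discretize(trace, post, n_bins, edges_strategy, pool_with = pre)
  list(network_label = network_label, mode = mode,
       h_pre = shannon_entropy(d_pre), h_post = shannon_entropy(d_post),
       delta_h = entropy_change(d_pre, d_post))
}
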