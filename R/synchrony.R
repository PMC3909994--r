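# Intra-network synchrony, metastability and related signal statistics.
#
# Two estimators of "intrinsic synchrony" are provided:
#   phase mode      — band-pass filter each voxel, take the analytic signal,
#                     and compute the Kuramoto order parameter
#                     R(t) = | mean_v exp(i theta_v(t)) |  in [0, 1];
#   amplitude mode  — z-score each voxel over the scan and report the
#                     cross-voxel standard deviation of the deviations from
#                     the network mean (dispersion; higher = less synchronous).
# Metastability is the unbiased temporal variance of the synchrony trace
# over a segment.

# Edge samples discarded from phase traces: the frequency-domain filter is
# applied circularly, so wrap-around transients contaminate both ends.
PHASE_TRIM <- 10L

#' Phase-mode synchrony trace of one network
#'
#' Each voxel series is linearly detrended, band-pass filtered with a
#' zero-phase frequency-domain (brick-wall) filter, and converted to its
#' analytic signal in the same FFT pass (negative frequencies zeroed,
#' in-band positive frequencies doubled). The per-timepoint synchrony is the
#' Kuramoto order parameter of the voxel phases. The first and last
#' `PHASE_TRIM` (10) timepoints are marked invalid because the circular
#' filter wraps the record ends.
#'
#' @param dataset a [voxel_ts_set()].
#' @param network_label network to analyze (must have at least 2 voxels).
#' @param band_low_hz,band_high_hz pass band in Hz; defaults 0.01–0.1, the
#'   conventional resting-state BOLD band. Must satisfy
#'   `0 < low < high <= Nyquist`.
#' @return an object of class `synchrony_trace` with fields `network_label`,
#'   `values` (length `n_timepoints`, `NA` outside the valid range), `mode`
#'   (`"phase"`), `valid_range` (0-based half-open segment) and
#'   `sampling_interval`.
#' @export
phase_trace <- function(dataset, network_label,
                        band_low_hz = 0.01, band_high_hz = 0.1) {
  stopifnot(inherits(dataset, "voxel_ts_set"))
  rows <- which(dataset$network_labels == network_label)
  if (length(rows) == 0L)
    stop("unknown network label '", network_label, "'")
  if (length(rows) < 2L)
    stop("phase synchrony is undefined for a single-voxel network ('",
         network_label, "')")
  nyquist <- 1 / (2 * dataset$sampling_interval)
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz &&
        band_high_hz <= nyquist))
    stop("pass band must satisfy 0 < low < high <= Nyquist (",
         signif(nyquist, 4), " Hz)")
  x <- t(dataset$data[rows, , drop = FALSE])   # time x voxels
  n_t <- nrow(x)
  if (n_t <= 2L * PHASE_TRIM + 1L)
    stop("scan too short for phase analysis (need > ", 2L * PHASE_TRIM + 1L,
         " timepoints)")
  x <- detrend_linear(x)
  analytic <- analytic_band_signal(x, dataset$sampling_interval,
                                   band_low_hz, band_high_hz)
  amp <- Mod(analytic)
  phasor <- analytic / ifelse(amp > 0, amp, 1)   # zero-amplitude -> 0 phasor
  r <- Mod(rowMeans(phasor))
  valid <- segment(PHASE_TRIM, n_t - PHASE_TRIM)
  vals <- rep(NA_real_, n_t)
  vals[segment_index(valid, n_t)] <- r[segment_index(valid, n_t)]
  new_synchrony_trace(network_label, vals, "phase", valid,
                      dataset$sampling_interval)
}

#' Amplitude-mode synchrony trace (cross-voxel dispersion)
#'
#' Voxels are z-scored over the full scan; the trace value at each timepoint
#' is the population (divide-by-N) standard deviation, across voxels, of the
#' deviation of each voxel's z-value from the network-mean z-value (so two
#' voxels at z = +1 and -1 give dispersion exactly 1). A value near 0 means
#' the voxels hug the network mean (high synchrony); large values mean the
#' voxels fluctuate erratically around it.
#'
#' @inheritParams phase_trace
#' @return a `synchrony_trace` with `mode = "amplitude"`; the whole scan is
#'   valid.
#' @export
amplitude_trace <- function(dataset, network_label) {
  stopifnot(inherits(dataset, "voxel_ts_set"))
  rows <- which(dataset$network_labels == network_label)
  if (length(rows) == 0L)
    stop("unknown network label '", network_label, "'")
  if (length(rows) < 2L)
    stop("dispersion is undefined for a single-voxel network ('",
         network_label, "')")
  x <- dataset$data[rows, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("cannot z-score zero-variance voxel (row ",
         rows[which(sds == 0)[1L]], ")")
  z <- (x - rowMeans(x)) / sds
  dev <- sweep(z, 2L, colMeans(z))
  disp <- sqrt(colMeans(dev^2))          # population sd across voxels
  new_synchrony_trace(network_label, disp, "amplitude",
                      segment(0L, ncol(x)), dataset$sampling_interval)
}

new_synchrony_trace <- function(network_label, values, mode, valid_range,
                                sampling_interval) {
  structure(list(network_label = network_label, values = values,
                 mode = mode, valid_range = valid_range,
                 sampling_interval = sampling_interval),
            class = "synchrony_trace")
}

#' @export
print.synchrony_trace <- function(x, ...) {
  cat("<synchrony_trace> network '", x$network_label, "', mode ", x$mode,
      ", ", length(x$values), " timepoints, valid [", x$valid_range[1L],
      ", ", x$valid_range[2L], ")\n", sep = "")
  invisible(x)
}

# remove per-column linear trends (time x series matrix)
detrend_linear <- function(x) {
  n <- nrow(x)
  t0 <- seq_len(n) - (n + 1) / 2            # centered time
  x <- sweep(x, 2L, colMeans(x))
  slope <- crossprod(t0, x) / sum(t0^2)
  x - outer(t0, drop(slope))
}

# Band-limited analytic signal of every column of x (time x series) in one
# frequency-domain pass: FFT, keep positive in-band frequencies doubled,
# zero everything else, inverse FFT.
analytic_band_signal <- function(x, dt, f_lo, f_hi) {
  n <- nrow(x)
  freqs <- (seq_len(n) - 1) / (n * dt)
  keep <- freqs >= f_lo & freqs <= f_hi & (seq_len(n) - 1) <= n / 2
  gain <- ifelse(keep, 2, 0)
  if (n %% 2 == 0 && keep[n / 2 + 1]) gain[n / 2 + 1] <- 1  # Nyquist bin
  f <- stats::mvfft(x) * gain
  stats::mvfft(f, inverse = TRUE) / n
}

#' Metastability of a synchrony trace
#'
#' The unbiased sample variance of the synchrony values over a segment —
#' the temporal variance of intra-network synchrony. High metastability
#' means the network's internal coordination is transient and unstable.
#'
#' @param trace a `synchrony_trace`.
#' @param seg a [segment()]; must lie inside the trace's valid range and
#'   contain at least 2 timepoints.
#' @return a non-negative number.
#' @export
metastability <- function(trace, seg) {
  stopifnot(inherits(trace, "synchrony_trace"))
  if (seg[1L] < trace$valid_range[1L] || seg[2L] > trace$valid_range[2L])
    stop("segment [", seg[1L], ", ", seg[2L],
         ") is not inside the trace's valid range [",
         trace$valid_range[1L], ", ", trace$valid_range[2L], ")")
  if (segment_length(seg) < 2L)
    stop("segment must contain at least 2 timepoints")
  stats::var(trace$values[segment_index(seg, length(trace$values))])
}

#' Percent change of a statistic, post vs. pre
#'
#' `(post - pre) / pre * 100`; requires a strictly positive baseline.
#'
#' @param pre_value baseline value (> 0).
#' @param post_value post value.
#' @return percent change (dimensionless).
#' @export
percent_change <- function(pre_value, post_value) {
  if (any(pre_value <= 0))
    stop("percent change undefined for baseline <= 0")
  (post_value - pre_value) / pre_value * 100
}

#' Pre/post metastability of one network
#'
#' Convenience wrapper: computes the synchrony trace in the requested mode,
#' clips the dataset's pre/post segments to the trace's valid range, and
#' returns pre- and post-infusion metastability with the percent change.
#'
#' @inheritParams phase_trace
#' @param mode `"amplitude"` (default; the deviation-from-network-mean
#'   dispersion estimator, which is also the better-calibrated one for
#'   pre/post percent-change inference) or `"phase"`.
#' @return list with `network_label`, `mode`, `pre_value`, `post_value`,
#'   `percent_change`.
#' @export
network_metastability <- function(dataset, network_label,
                                  mode = c("amplitude", "phase"),
                                  band_low_hz = 0.01, band_high_hz = 0.1) {
  mode <- match.arg(mode)
  trace <- if (mode == "phase")
    phase_trace(dataset, network_label, band_low_hz, band_high_hz)
  else amplitude_trace(dataset, network_label)
  pre <- segment_intersect(pre_segment(dataset), trace$valid_range)
  post <- segment_intersect(post_segment(dataset), trace$valid_range)
  if (is.null(pre) || is.null(post))
    stop("pre or post segment does not overlap the trace's valid range")
  pre_v <- metastability(trace, pre)
  post_v <- metastability(trace, post)
  list(network_label = network_label, mode = mode,
       pre_value = pre_v, post_value = post_v,
       percent_change = percent_change(pre_v, post_v))
}

#' Pre/post signal-variance change of one region
#'
#' Sample variance of a single region's raw signal in two segments, with
#' the percent change — the regional signal-variance statistic used for the
#' hippocampal/parahippocampal variance-increase analysis.
#'
#' @param series a [region_ts()].
#' @param region region name.
#' @param pre_seg,post_seg segments (default: the series' pre/post infusion
#'   segments).
#' @return list with `region`, `pre_variance`, `post_variance`,
#'   `percent_change`.
#' @export
regional_variance_change <- function(series, region,
                                     pre_seg = pre_segment(series),
                                     post_seg = post_segment(series)) {
  stopifnot(inherits(series, "region_ts"))
  row <- match(region, series$region_names)
  if (is.na(row)) stop("unknown region '", region, "'")
  if (segment_length(pre_seg) < 2L || segment_length(post_seg) < 2L)
    stop("each segment must contain at least 2 timepoints")
  n <- ncol(series$data)
  pre_v <- stats::var(series$data[row, segment_index(pre_seg, n)])
  post_v <- stats::var(series$data[row, segment_index(post_seg, n)])
  list(region = region, pre_variance = pre_v, post_variance = post_v,
       percent_change = percent_change(pre_v, post_v))
}

#' Between-network (anti)correlation
#'
#' Pearson correlation of two network-mean time series over a segment —
#' e.g. the default-mode vs. task-positive anticorrelation.
#'
#' @param series_a,series_b numeric vectors of equal length (network mean
#'   signals).
#' @param seg optional [segment()] restricting the comparison.
#' @return Pearson r in `[-1, 1]`.
#' @export
network_anticorrelation <- function(series_a, series_b, seg = NULL) {
  if (length(series_a) != length(series_b))
    stop("series must have equal length")
  if (!is.null(seg)) {
    idx <- segment_index(seg, length(series_a))
    series_a <- series_a[idx]; series_b <- series_b[idx]
  }
  if (length(series_a) < 3L)
    stop("need at least 3 timepoints")
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("correlation undefined for a constant series")
  stats::cor(series_a, series_b)
}
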