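#' Labeled voxel-by-timepoint dataset
#'
#' The unit of the network synchrony/entropy analyses: a numeric matrix of
#' voxel time series (rows = voxels, columns = timepoints) with one network
#' label per voxel, the sampling interval in seconds, and optionally the
#' infusion onset/duration (in timepoints) of a mid-scan drug infusion.
#'
#' All time indexing in this package is 0-based and segments are half-open
#' `[start, end)` integer intervals, so a 240-timepoint scan spans
#' `[0, 240)` and an infusion starting at timepoint 120 lasting 20
#' timepoints occupies `[120, 140)`.
#'
#' @param data numeric matrix, voxels x timepoints, finite values only.
#' @param network_labels character vector, one label per row of `data`.
#' @param sampling_interval sampling interval (repetition time) in seconds.
#' @param infusion_onset 0-based timepoint index of infusion start, or `NULL`.
#' @param infusion_duration infusion length in timepoints (default 0).
#' @param subject_id optional subject identifier.
#' @param condition optional condition tag (e.g. `"placebo"`, `"drug"`).
#' @return an object of class `voxel_ts_set`.
#' @export
voxel_ts_set <- function(data, network_labels, sampling_interval,
                         infusion_onset = NULL, infusion_duration = 0L,
                         subject_id = NULL, condition = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("'data' must be a numeric matrix with only finite values")
  network_labels <- as.character(network_labels)
  if (length(network_labels) != nrow(data))
    stop("need one network label per voxel: ", nrow(data), " voxels but ",
         length(network_labels), " labels")
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      sampling_interval <= 0)
    stop("'sampling_interval' must be a single positive number (seconds)")
  n_t <- ncol(data)
  if (!is.null(infusion_onset)) {
    infusion_onset <- as.integer(infusion_onset)
    infusion_duration <- as.integer(infusion_duration)
    if (infusion_onset < 0L || infusion_onset >= n_t)
      stop("'infusion_onset' must lie in [0, ", n_t, ")")
    if (infusion_duration < 0L ||
        infusion_onset + infusion_duration >= n_t)
      stop("infusion window [", infusion_onset, ", ",
           infusion_onset + infusion_duration,
           ") must end before the last timepoint")
  }
  structure(
    list(data = data, network_labels = network_labels,
         sampling_interval = sampling_interval,
         infusion_onset = infusion_onset,
         infusion_duration = if (is.null(infusion_onset)) NULL
                             else infusion_duration,
         subject_id = subject_id, condition = condition),
    class = "voxel_ts_set")
}

#' @export
print.voxel_ts_set <- function(x, ...) {
  cat("<voxel_ts_set> ", nrow(x$data), " voxels x ", ncol(x$data),
      " timepoints (TR ", x$sampling_interval, " s)\n", sep = "")
  tab <- table(x$network_labels)
  cat("  networks: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$infusion_onset))
    cat("  infusion: [", x$infusion_onset, ", ",
        x$infusion_onset + x$infusion_duration, ")\n", sep = "")
  if (!is.null(x$subject_id))
    cat("  subject: ", x$subject_id,
        if (!is.null(x$condition)) paste0(" (", x$condition, ")"), "\n",
        sep = "")
  invisible(x)
}

#' Named-region time-series matrix
#'
#' Container for small ROI sets (e.g. the four-node bilateral
#' hippocampus / anterior cingulate analysis): a regions x timepoints
#' numeric matrix with distinct region names.
#'
#' @param data numeric matrix, regions x timepoints, finite values only.
#' @param region_names character vector of distinct region names, one per row.
#' @param sampling_interval sampling interval in seconds.
#' @param infusion_onset 0-based infusion start timepoint, or `NULL`.
#' @param infusion_duration infusion length in timepoints.
#' @param subject_id optional subject identifier.
#' @param condition optional condition tag.
#' @param regime_sequence optional integer vector (one regime index per
#'   timepoint) recording the true hidden coupling regime when the data are
#'   synthetic; kept for validation, ignored by the analyses.
#' @return an object of class `region_ts`.
#' @export
region_ts <- function(data, region_names, sampling_interval,
                      infusion_onset = NULL, infusion_duration = 0L,
                      subject_id = NULL, condition = NULL,
                      regime_sequence = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("'data' must be a numeric matrix with only finite values")
  region_names <- as.character(region_names)
  if (length(region_names) != nrow(data))
    stop("need one region name per row")
  if (anyDuplicated(region_names))
    stop("region names must be distinct")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop("'sampling_interval' must be positive")
  n_t <- ncol(data)
  if (!is.null(infusion_onset)) {
    infusion_onset <- as.integer(infusion_onset)
    infusion_duration <- as.integer(infusion_duration)
    if (infusion_onset < 0L || infusion_onset >= n_t)
      stop("'infusion_onset' must lie in [0, ", n_t, ")")
    if (infusion_onset + infusion_duration >= n_t)
      stop("infusion window must end before the last timepoint")
  }
  rownames(data) <- region_names
  structure(
    list(data = data, region_names = region_names,
         sampling_interval = sampling_interval,
         infusion_onset = infusion_onset,
         infusion_duration = if (is.null(infusion_onset)) NULL
                             else infusion_duration,
         subject_id = subject_id, condition = condition,
         regime_sequence = regime_sequence),
    class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat("<region_ts> ", nrow(x$data), " regions x ", ncol(x$data),
      " timepoints (TR ", x$sampling_interval, " s)\n  regions: ",
      paste(x$region_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# --- segments -------------------------------------------------------------

#' Construct and query half-open time segments
#'
#' Segments are length-2 integer vectors `c(start, end)` interpreted as the
#' 0-based half-open interval `[start, end)`.
#'
#' @param start 0-based first timepoint of the segment.
#' @param end 0-based one-past-last timepoint.
#' @return an integer vector `c(start, end)`.
#' @export
segment <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("segment bounds must be single integers")
  if (end <= start) stop("segment [", start, ", ", end, ") is empty")
  c(start, end)
}

segment_length <- function(seg) seg[2L] - seg[1L]

# 1-based R column indices of a segment, checked against n timepoints
segment_index <- function(seg, n) {
  if (seg[1L] < 0L || seg[2L] > n)
    stop("segment [", seg[1L], ", ", seg[2L],
         ") out of range for ", n, " timepoints")
  (seg[1L] + 1L):seg[2L]
}

#' Pre- and post-infusion segments of a dataset
#'
#' The pre segment is `[0, infusion_onset)` and the post segment is
#' `[infusion_onset + infusion_duration, n_timepoints)`: the infusion window
#' itself is treated as a transition period and belongs to neither.
#'
#' @param x a `voxel_ts_set` or `region_ts` with an infusion onset.
#' @return a segment (see [segment()]).
#' @export
pre_segment <- function(x) {
  if (is.null(x$infusion_onset))
    stop("dataset has no infusion onset; pre/post segments undefined")
  segment(0L, x$infusion_onset)
}

#' @rdname pre_segment
#' @export
post_segment <- function(x) {
  if (is.null(x$infusion_onset))
    stop("dataset has no infusion onset; pre/post segments undefined")
  segment(x$infusion_onset + x$infusion_duration, ncol(x$data))
}

# intersection of two segments; NULL when empty
segment_intersect <- function(a, b) {
  s <- max(a[1L], b[1L]); e <- min(a[2L], b[2L])
  if (e <= s) NULL else segment(s, e)
}
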