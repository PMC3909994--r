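#' Read a delimited time-series bundle
#'
#' The delimited on-disk format is a three-file bundle: a tab-separated
#' numeric matrix with no header (rows = voxels, columns = timepoints), a
#' sidecar label file with one network label per matrix row, and an optional
#' `key = value` metadata file carrying `sampling_interval`,
#' `infusion_onset`, `infusion_duration`, `subject_id` and `condition`.
#' Explicit arguments override metadata-file values.
#'
#' @param path_matrix path to the TSV matrix (no header row).
#' @param path_labels path to the label sidecar (one label per line).
#' @param path_meta optional path to a `key = value` metadata file.
#' @param sampling_interval,infusion_onset,infusion_duration,subject_id,condition
#'   metadata overrides; `sampling_interval` is required if no metadata file
#'   provides it.
#' @param label_set optional declared label set; any label outside it is a
#'   validation error.
#' @return a [voxel_ts_set()].
#' @export
read_matrix_dataset <- function(path_matrix, path_labels, path_meta = NULL,
                                sampling_interval = NULL,
                                infusion_onset = NULL,
                                infusion_duration = NULL,
                                subject_id = NULL, condition = NULL,
                                label_set = NULL) {
  raw <- utils::read.table(path_matrix, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell in ", path_matrix, " at row ", bad[1L],
         ", column ", bad[2L], ": '", as.matrix(raw)[bad[1L], bad[2L]], "'")
  }
  labels <- readLines(path_labels)
  labels <- labels[nzchar(trimws(labels))]
  labels <- trimws(labels)
  if (length(labels) != nrow(mat))
    stop("row-count mismatch: matrix has ", nrow(mat), " rows but ",
         path_labels, " has ", length(labels), " labels")
  if (!is.null(label_set) && !all(labels %in% label_set)) {
    unknown <- setdiff(unique(labels), label_set)
    stop("unknown network label(s): ", paste(unknown, collapse = ", "))
  }
  meta <- if (!is.null(path_meta)) read_metadata_file(path_meta) else list()
  pick <- function(override, key, coerce = identity)
    if (!is.null(override)) override
    else if (!is.null(meta[[key]])) coerce(meta[[key]]) else NULL
  si <- pick(sampling_interval, "sampling_interval", as.numeric)
  if (is.null(si))
    stop("sampling_interval missing: give it as an argument or in the ",
         "metadata file")
  voxel_ts_set(mat, labels, si,
               infusion_onset = pick(infusion_onset, "infusion_onset",
                                     as.integer),
               infusion_duration = {
                 d <- pick(infusion_duration, "infusion_duration",
                           as.integer)
                 if (is.null(d)) 0L else d
               },
               subject_id = pick(subject_id, "subject_id"),
               condition = pick(condition, "condition"))
}

#' Write a dataset as a delimited bundle
#'
#' Inverse of [read_matrix_dataset()]: writes `<prefix>_data.tsv`,
#' `<prefix>_labels.txt` and `<prefix>_meta.txt`.
#'
#' @param x a `voxel_ts_set`.
#' @param prefix file path prefix for the three output files.
#' @return invisibly, the three paths written.
#' @export
write_matrix_dataset <- function(x, prefix) {
  stopifnot(inherits(x, "voxel_ts_set"))
  paths <- paste0(prefix, c("_data.tsv", "_labels.txt", "_meta.txt"))
  utils::write.table(format(x$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     paths[1L], sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(x$network_labels, paths[2L])
  meta <- c(paste("sampling_interval =", x$sampling_interval),
            if (!is.null(x$infusion_onset))
              c(paste("infusion_onset =", x$infusion_onset),
                paste("infusion_duration =", x$infusion_duration)),
            if (!is.null(x$subject_id))
              paste("subject_id =", x$subject_id),
            if (!is.null(x$condition))
              paste("condition =", x$condition))
  writeLines(meta, paths[3L])
  invisible(paths)
}

read_metadata_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed metadata line in ", path, ": '", lines[bad][1L], "'")
  out <- lapply(kv, function(p) trimws(p[2L]))
  names(out) <- vapply(kv, function(p) trimws(p[1L]), character(1))
  out
}

#' Read a 4D NIfTI image with an integer network-label volume
#'
#' Voxels with a nonzero label in the 3D label volume are extracted from the
#' 4D image and flattened in column-major scan order (x fastest, then y,
#' then z), so voxel row indices are reproducible. Label 0 is background and
#' is excluded. The sampling interval defaults to the image's time-step
#' header field (`pixdim[4]`).
#'
#' @param path_4d path to the 4D NIfTI-1 image.
#' @param path_labels path to a 3D integer NIfTI-1 label volume on the same
#'   grid.
#' @param sampling_interval override for the header time step, in seconds.
#' @param infusion_onset,infusion_duration,subject_id,condition metadata.
#' @return a [voxel_ts_set()]; labels are the character form of the integer
#'   label values.
#' @export
read_nifti_dataset <- function(path_4d, path_labels,
                               sampling_interval = NULL,
                               infusion_onset = NULL,
                               infusion_duration = 0L,
                               subject_id = NULL, condition = NULL) {
  img <- RNifti::readNifti(path_4d)
  lab <- RNifti::readNifti(path_labels)
  dimg <- dim(img); dlab <- dim(lab)
  if (length(dimg) != 4L)
    stop("expected a 4D image, got ", length(dimg), " dimensions")
  if (length(dlab) == 4L && dlab[4L] == 1L) {
    lab <- array(lab, dim = dlab[1:3]); dlab <- dim(lab)
  }
  if (length(dlab) != 3L)
    stop("expected a 3D label volume, got ", length(dlab), " dimensions")
  if (!all(dimg[1:3] == dlab))
    stop("grid mismatch: image grid ", paste(dimg[1:3], collapse = "x"),
         " vs label grid ", paste(dlab, collapse = "x"))
  lab_int <- round(as.vector(lab))
  keep <- which(lab_int != 0L)          # column-major: x fastest
  if (length(keep) == 0L)
    stop("label volume selects no voxels (all labels zero)")
  n_vox <- prod(dimg[1:3])
  mat <- matrix(as.vector(img), nrow = n_vox, ncol = dimg[4L])[keep, ,
                                                               drop = FALSE]
  if (is.null(sampling_interval)) {
    sampling_interval <- RNifti::pixdim(img)[4L]
    if (!is.finite(sampling_interval) || sampling_interval <= 0)
      stop("image header has no usable time step; pass sampling_interval")
  }
  voxel_ts_set(mat, as.character(lab_int[keep]), sampling_interval,
               infusion_onset = infusion_onset,
               infusion_duration = infusion_duration,
               subject_id = subject_id, condition = condition)
}

#' Mean time series of one network
#'
#' Per-timepoint arithmetic mean over all voxels carrying the given label.
#'
#' @param dataset a `voxel_ts_set`.
#' @param network_label the label to average.
#' @return numeric vector of length `n_timepoints`.
#' @export
extract_network_mean <- function(dataset, network_label) {
  stopifnot(inherits(dataset, "voxel_ts_set"))
  rows <- dataset$network_labels == network_label
  if (!any(rows))
    stop("unknown network label '", network_label, "'")
  colMeans(dataset$data[rows, , drop = FALSE])
}
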