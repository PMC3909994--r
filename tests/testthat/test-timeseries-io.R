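test_that("delimited bundle round-trips and preserves label alignment", {
  set.seed(11)
  x <- voxel_ts_set(matrix(rnorm(6 * 20), nrow = 6),
                    rep(c("net_a", "net_b"), each = 3),
                    sampling_interval = 3, infusion_onset = 10,
                    infusion_duration = 2, subject_id = "sub-01",
                    condition = "placebo")
  prefix <- file.path(tempdir(), "bundle")
  write_matrix_dataset(x, prefix)
  y <- read_matrix_dataset(paste0(prefix, "_data.tsv"),
                           paste0(prefix, "_labels.txt"),
                           paste0(prefix, "_meta.txt"))
  expect_equal(y$data, x$data, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(y$network_labels, x$network_labels)
  expect_identical(y$infusion_onset, 10L)
  expect_identical(y$infusion_duration, 2L)
  expect_identical(y$subject_id, "sub-01")
  expect_identical(y$condition, "placebo")
  expect_equal(table(y$network_labels)[["net_a"]], 3)
})

test_that("malformed delimited input is reported with coordinates", {
  m_path <- file.path(tempdir(), "m.tsv")
  l_path <- file.path(tempdir(), "l.txt")
  writeLines(c("1\t2\t3", "4\tfive\t6"), m_path)
  writeLines(c("a", "a"), l_path)
  expect_error(read_matrix_dataset(m_path, l_path, sampling_interval = 3),
               "row 2, column 2")
  writeLines(c("1\t2\t3", "4\t5\t6"), m_path)
  writeLines("a", l_path)
  expect_error(read_matrix_dataset(m_path, l_path, sampling_interval = 3),
               "row-count mismatch")
  writeLines(c("a", "b"), l_path)
  expect_error(read_matrix_dataset(m_path, l_path, sampling_interval = 3,
                                   label_set = c("a", "c")),
               "unknown network label")
})

test_that("NIfTI extraction flattens labeled voxels deterministically", {
  skip_if_not_installed("RNifti")
  dir <- tempdir()
  img_path <- file.path(dir, "img.nii")
  lab_path <- file.path(dir, "lab.nii")
  arr <- array(0, dim = c(2, 2, 2, 10))
  lab <- array(0L, dim = c(2, 2, 2))
  # four voxels of label 1, two of label 2, in known grid positions
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L; lab[1, 2, 1] <- 1L
  lab[2, 2, 1] <- 1L
  lab[1, 1, 2] <- 2L; lab[2, 1, 2] <- 2L
  # constant, position-coded voxel values
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    arr[i, j, k, ] <- i * 100 + j * 10 + k
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, 3)), img_path)
  RNifti::writeNifti(RNifti::asNifti(lab), lab_path)
  ds <- read_nifti_dataset(img_path, lab_path, sampling_interval = 3)
  expect_equal(nrow(ds$data), 6)
  expect_equal(unname(table(ds$network_labels)[c("1", "2")]),
               c(4L, 2L), ignore_attr = TRUE)
  # column-major order: x fastest, then y, then z
  expect_equal(unname(ds$data[, 1]), c(111, 211, 121, 221, 112, 212))
  expect_true(all(ds$data == ds$data[, 1]))  # constants preserved

  lab_bad <- array(1L, dim = c(3, 2, 2))
  lab_bad_path <- file.path(dir, "lab_bad.nii")
  RNifti::writeNifti(RNifti::asNifti(lab_bad), lab_bad_path)
  expect_error(read_nifti_dataset(img_path, lab_bad_path,
                                  sampling_interval = 3), "grid mismatch")
  lab0 <- array(0L, dim = c(2, 2, 2))
  lab0_path <- file.path(dir, "lab0.nii")
  RNifti::writeNifti(RNifti::asNifti(lab0), lab0_path)
  expect_error(read_nifti_dataset(img_path, lab0_path,
                                  sampling_interval = 3), "no voxels")
})

test_that("network mean extraction matches brute-force recomputation", {
  x <- voxel_ts_set(rbind(c(1, 5), c(3, 7), c(10, 20)),
                    c("a", "a", "b"), sampling_interval = 2)
  expect_equal(extract_network_mean(x, "a"), c(2, 6))
  expect_equal(extract_network_mean(x, "b"), c(10, 20))  # single voxel
  expect_error(extract_network_mean(x, "zzz"), "unknown network label")

  set.seed(21)
  z <- matrix(rnorm(3 * 15), nrow = 3)
  z <- (z - rowMeans(z)) / apply(z, 1, sd)
  ds <- voxel_ts_set(z, rep("n", 3), sampling_interval = 1)
  manual <- sapply(seq_len(15), function(t) (z[1, t] + z[2, t] + z[3, t]) / 3)
  expect_equal(extract_network_mean(ds, "n"), manual, tolerance = 1e-12)
})

test_that("container invariants and segment conventions are enforced", {
  expect_error(voxel_ts_set(matrix(c(1, NA), 1), "a", 1), "finite")
  expect_error(voxel_ts_set(matrix(1:4, 2), c("a"), 1), "one network label")
  expect_error(voxel_ts_set(matrix(1:4, 2), c("a", "b"), 1,
                            infusion_onset = 2), "infusion")
  expect_error(region_ts(matrix(1:4, 2), c("r", "r"), 1), "distinct")
  x <- voxel_ts_set(matrix(rnorm(2 * 240), 2), c("a", "b"), 3,
                    infusion_onset = 120, infusion_duration = 20)
  expect_identical(pre_segment(x), c(0L, 120L))
  expect_identical(post_segment(x), c(140L, 240L))
  expect_error(segment(5, 5), "empty")
})
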