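test_that("generation is deterministic given the seed", {
  cfg <- test_config(seed = 5, condition = "drug_like")
  a <- generate_voxel_dataset(cfg)
  b <- generate_voxel_dataset(cfg)
  expect_identical(a$data, b$data)
  r1 <- generate_roi_dataset(cfg)
  r2 <- generate_roi_dataset(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$regime_sequence, r2$regime_sequence)
  expect_false(identical(
    generate_voxel_dataset(test_config(seed = 6))$data, a$data))
})

test_that("invalid configurations name the violated invariant", {
  expect_error(generator_config(infusion_onset = 230,
                                infusion_duration = 20),
               "infusion_onset \\+ infusion_duration")
  expect_error(generator_config(noise_sd = 0), "noise_sd")
  expect_error(generator_config(switch_rate = 1.5), "switch rates")
  expect_error(generator_config(n_regimes = 0), "n_regimes")
  expect_error(generator_config(sampling_interval = -1),
               "sampling_interval")
  expect_error(generator_config(coupling_sd_post = -0.1),
               "coupling_sd_post")
  expect_error(generator_config(n_rois = 4, n_regimes = 100),
               "at most 64")
})

test_that("placebo-like coupling is constant: the condition flag and
           coupling_sd_post leave the placebo process untouched", {
  base <- generate_voxel_dataset(test_config(seed = 3,
                                             coupling_sd_post = 0.2))
  alt <- generate_voxel_dataset(test_config(seed = 3,
                                            coupling_sd_post = 0.7))
  expect_identical(base$data, alt$data)     # placebo ignores the drift sd
  drug0 <- generate_voxel_dataset(test_config(seed = 3,
                                              condition = "drug_like",
                                              coupling_sd_post = 0))
  expect_identical(base$data, drug0$data)   # zero drift = placebo process
})

test_that("drug-like coupling drift alters only association-like networks", {
  pla <- generate_voxel_dataset(test_config(seed = 9))
  dru <- generate_voxel_dataset(test_config(seed = 9,
                                            condition = "drug_like"))
  cfg <- test_config(seed = 9)
  sensory <- cfg$network_names %in% cfg$sensory_networks
  for (n in seq_along(cfg$network_names)) {
    rows <- which(pla$network_labels == cfg$network_names[n])
    if (sensory[n])
      expect_identical(pla$data[rows, ], dru$data[rows, ])
    else
      expect_false(identical(pla$data[rows, ], dru$data[rows, ]))
  }
  # pre-infusion segment is identical in every network: the drug acts only
  # from the infusion onset onward
  pre_cols <- 1:120
  expect_identical(pla$data[, pre_cols], dru$data[, pre_cols])
})

test_that("coupling drift raises post-infusion dispersion metastability
           (Monte-Carlo margin)", {
  post_ms <- function(sd_post, seed) {
    cfg <- test_config(seed = seed, condition = "drug_like",
                       coupling_sd_post = sd_post)
    d <- generate_voxel_dataset(cfg)
    network_metastability(d, "default_mode", "amplitude")$post_value
  }
  with_drift <- vapply(1:200, function(s) post_ms(0.5, s), numeric(1))
  without <- vapply(1:200, function(s) post_ms(0.0, s), numeric(1))
  # oracle runs put the ratio of means near 3.7; require a 2x margin
  expect_gt(mean(with_drift), 2 * mean(without))
})

test_that("regime dynamics follow the configured Markov chain", {
  cfg <- test_config(seed = 4, n_regimes = 1, switch_rate = 0)
  r <- generate_roi_dataset(cfg)
  expect_true(all(r$regime_sequence == r$regime_sequence[1]))
  cfg2 <- test_config(seed = 4, n_regimes = 3, switch_rate = 0.5)
  r2 <- generate_roi_dataset(cfg2)
  expect_true(all(r2$regime_sequence %in% 1:3))
  expect_gt(length(unique(r2$regime_sequence)), 1)
  # drug-like scans switch to the richer dynamics only post-infusion
  cfg3 <- test_config(seed = 4, condition = "drug_like", n_regimes = 8,
                      switch_rate = 0.5, n_regimes_pre = 2,
                      switch_rate_pre = 0)
  r3 <- generate_roi_dataset(cfg3)
  pre <- r3$regime_sequence[1:120]
  expect_true(all(pre == pre[1]) && pre[1] <= 2)
})

test_that("richer regime dynamics raise motif-sequence entropy
           (Monte-Carlo margin)", {
  h0 <- function(nr, sw, seed) {
    cfg <- test_config(seed = seed, n_regimes = nr, switch_rate = sw)
    r <- generate_roi_dataset(cfg)
    motif_entropy(suppressMessages(
      motif_sequence(r, seg = post_segment(r))), 0)
  }
  drug <- vapply(1:100, function(s) h0(8, 0.2, s), numeric(1))
  plac <- vapply(1:100, function(s) h0(2, 0.05, s), numeric(1))
  # oracle runs put the means near 2.8 vs 1.8 bits; require a 0.5-bit margin
  expect_gt(mean(drug), mean(plac) + 0.5)
})

test_that("condition pairs are matched, labeled and pairwise distinct", {
  pair <- generate_condition_pair(test_config(seed = 2), n_subjects = 4,
                                  what = "roi")
  expect_length(pair$subjects, 4)
  ids <- vapply(pair$subjects, `[[`, character(1), "subject_id")
  expect_identical(ids, sprintf("sub-%02d", 1:4))
  for (s in pair$subjects) {
    expect_identical(s$placebo$roi$condition, "placebo_like")
    expect_identical(s$drug$roi$condition, "drug_like")
  }
  mats <- lapply(pair$subjects, function(s) s$placebo$roi$data)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(mats[[i]], mats[[j]]))
  expect_error(generate_condition_pair(test_config(), n_subjects = 1),
               "n_subjects")
})
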