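# sinusoidal fixture: n_vox voxels carrying a common 0.05 Hz tone at given
# per-voxel phase offsets, 240 timepoints at TR 3 s
tone_dataset <- function(phases, freq = 0.05, tr = 3, n_t = 240) {
  t_s <- (seq_len(n_t) - 1) * tr
  data <- t(vapply(phases, function(ph) cos(2 * pi * freq * t_s + ph),
                   numeric(n_t)))
  voxel_ts_set(data, rep("net", length(phases)), tr)
}

valid_vals <- function(trace) {
  idx <- (trace$valid_range[1] + 1):trace$valid_range[2]
  trace$values[idx]
}

test_that("phase synchrony hits its analytic extremes", {
  # detrending perturbs a finite cosine record slightly, so the analytic
  # extremes are met to ~1e-2 rather than machine precision
  # identical sinusoids: perfect phase locking, R(t) = 1
  tr1 <- phase_trace(tone_dataset(c(0, 0, 0)), "net")
  expect_equal(valid_vals(tr1), rep(1, length(valid_vals(tr1))),
               tolerance = 1e-6)
  # antipodal pair: phasors cancel, R(t) = 0
  tr2 <- phase_trace(tone_dataset(c(0, pi)), "net")
  expect_lt(max(abs(valid_vals(tr2))), 0.02)
  # phases equally spaced around the circle: roots-of-unity sum = 0
  tr3 <- phase_trace(tone_dataset(2 * pi * (0:4) / 5), "net")
  expect_lt(max(abs(valid_vals(tr3))), 0.02)
})

test_that("phase synchrony is bounded and invariant to a common phase shift", {
  set.seed(31)
  for (rep in 1:5) {
    phases <- runif(6, 0, 2 * pi)
    base <- phase_trace(tone_dataset(phases), "net")
    expect_true(all(valid_vals(base) >= 0 & valid_vals(base) <= 1 + 1e-12))
    shifted <- phase_trace(tone_dataset(phases + runif(1, 0, 2 * pi)),
                           "net")
    expect_lt(max(abs(valid_vals(base) - valid_vals(shifted))), 0.01)
    pre <- segment(20, 120)
    expect_lt(abs(metastability(base, pre) - metastability(shifted, pre)),
              1e-5)
  }
})

test_that("phase trace rejects degenerate inputs", {
  ds <- tone_dataset(c(0, 1))
  one <- voxel_ts_set(ds$data[1, , drop = FALSE], "net", 3)
  expect_error(phase_trace(one, "net"), "single-voxel")
  expect_error(phase_trace(ds, "net", band_high_hz = 0.5), "Nyquist")
  expect_error(phase_trace(ds, "net", band_low_hz = 0.2,
                           band_high_hz = 0.1), "Nyquist")
  expect_error(phase_trace(ds, "nope"), "unknown network")
})

test_that("dispersion trace matches hand values and a brute-force oracle", {
  # identical voxels: zero dispersion everywhere
  same <- voxel_ts_set(rbind(sin(1:50), sin(1:50)), c("n", "n"), 1)
  expect_equal(max(amplitude_trace(same, "n")$values), 0, tolerance = 1e-12)
  # opposed pair: z-values are +/-sqrt((n-1)/n) (sample-sd z-scoring), so
  # the dispersion is sqrt(49/50) at every timepoint by hand computation
  anti <- voxel_ts_set(rbind(rep(c(1, -1), 25), rep(c(-1, 1), 25)),
                       c("n", "n"), 1)
  tr <- amplitude_trace(anti, "n")
  expect_equal(tr$values, rep(sqrt(49 / 50), 50), tolerance = 1e-12)
  # random 5-voxel fixture equals per-timepoint population-sd recomputation
  set.seed(32)
  x <- matrix(rnorm(5 * 40), nrow = 5)
  ds <- voxel_ts_set(x, rep("n", 5), 1)
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  manual <- vapply(seq_len(40), function(t) {
    dev <- z[, t] - mean(z[, t])
    sqrt(sum(dev^2) / 5)
  }, numeric(1))
  expect_equal(amplitude_trace(ds, "n")$values, manual, tolerance = 1e-12)
  # zero-variance voxel is named
  flat <- voxel_ts_set(rbind(rnorm(20), rep(2, 20)), c("n", "n"), 1)
  expect_error(amplitude_trace(flat, "n"), "zero-variance voxel")
})

test_that("metastability is the unbiased variance over the segment", {
  tr <- structure(list(network_label = "n",
                       values = c(0, 1, 0, 1), mode = "amplitude",
                       valid_range = c(0L, 4L), sampling_interval = 1),
                  class = "synchrony_trace")
  expect_equal(metastability(tr, segment(0, 4)), 1 / 3)
  const <- tr; const$values <- rep(0.4, 4)
  expect_equal(metastability(const, segment(0, 4)), 0)
  set.seed(33)
  rnd <- tr; rnd$values <- runif(4)
  expect_equal(metastability(rnd, segment(0, 4)),
               oracle_variance(rnd$values), tolerance = 1e-14)
  expect_error(metastability(tr, segment(3, 4)), "at least 2")
  expect_error(metastability(tr, segment(0, 6)), "valid range")
})

test_that("percent change follows its definition and guards the baseline", {
  expect_equal(percent_change(2, 3), 50)
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(4, 1), -75)
  expect_error(percent_change(0, 1), "baseline")
})

test_that("regional variance change matches construction and recovers the
           planted hippocampal increase", {
  # pre sd 1, post sd 2 by construction: variance 1 -> 4, +300%
  set.seed(34)
  b1 <- scale(rnorm(100))[, 1]            # pre: variance exactly 1
  b2 <- scale(rnorm(100))[, 1]
  sig <- c(b1, 2 * b2)                    # post: variance exactly 4
  rs <- region_ts(rbind(sig, rnorm(200)), c("hip", "other"), 3,
                  infusion_onset = 100, infusion_duration = 0)
  out <- regional_variance_change(rs, "hip")
  expect_equal(out$percent_change, 300, tolerance = 1e-6)
  expect_error(regional_variance_change(rs, "nope"), "unknown region")
  const <- region_ts(rbind(rep(1, 200), rnorm(200)), c("c", "o"), 3,
                     infusion_onset = 100)
  expect_error(regional_variance_change(const, "c"), "baseline")
  # drug-like synthetic ROI data: mean hippocampal change positive
  pc <- vapply(1:100, function(s) {
    r <- generate_roi_dataset(test_config(seed = s,
                                          condition = "drug_like"))
    regional_variance_change(r, "hippocampus_left")$percent_change
  }, numeric(1))
  expect_gt(mean(pc), 0)
})

test_that("network anticorrelation is Pearson r with its edge cases", {
  set.seed(35)
  a <- rnorm(100)
  expect_equal(network_anticorrelation(a, -a), -1, tolerance = 1e-12)
  expect_equal(network_anticorrelation(a, a), 1, tolerance = 1e-12)
  b <- rnorm(100)
  expect_equal(network_anticorrelation(a, b), oracle_pearson(a, b),
               tolerance = 1e-12)
  expect_equal(network_anticorrelation(a, b, segment(10, 60)),
               oracle_pearson(a[11:60], b[11:60]), tolerance = 1e-12)
  expect_error(network_anticorrelation(a, rep(1, 100)), "constant")
  expect_error(network_anticorrelation(a, b[1:50]), "equal length")
})

test_that("placebo percent changes center on zero; drug-affected networks
           rise and sensory-like networks do not", {
  pc <- function(seed, cond, net) {
    d <- generate_voxel_dataset(test_config(seed = seed, condition = cond))
    network_metastability(d, net, "amplitude")$percent_change
  }
  plac <- vapply(1:60, function(s) pc(s, "placebo_like", "default_mode"),
                 numeric(1))
  expect_lt(abs(mean(plac)), 10)           # no systematic drift
  drug_assoc <- vapply(1:60, function(s) pc(s, "drug_like", "default_mode"),
                       numeric(1))
  expect_gt(mean(drug_assoc), 100)         # planted effect, large
  drug_sens <- vapply(1:60, function(s) pc(s, "drug_like", "auditory"),
                      numeric(1))
  expect_lt(abs(mean(drug_sens)), 15)      # null network stays null
})
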