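#' Configuration for the synthetic BOLD-like generator
#'
#' Describes a single simulated resting-state scan in a placebo-controlled
#' infusion design: `n_networks` labeled networks of voxels sharing a latent
#' low-frequency signal, a mid-scan infusion window, and a small ROI set
#' whose pairwise coupling switches among hidden regimes. Defaults emulate a
#' 12-minute scan sampled every 3 s (240 timepoints) with a 60-s infusion
#' beginning midway (`[120, 140)`), nine canonical resting-state networks,
#' and a four-node limbic/paralimbic ROI set (bilateral hippocampus and
#' anterior cingulate).
#'
#' Condition semantics:
#' \itemize{
#'   \item `placebo_like`: the voxel-to-network coupling weights are
#'     constant across the whole scan, and the ROI regime dynamics use
#'     (`n_regimes`, `switch_rate`) throughout — the process is stationary,
#'     so pre- and post-infusion segments are draws from the same process.
#'   \item `drug_like`: from the infusion onset onward, voxel coupling
#'     weights in the non-sensory ("association-like") networks become a
#'     slowly drifting stochastic process with stationary standard deviation
#'     `coupling_sd_post`, and the ROI regime dynamics switch from the
#'     baseline (`n_regimes_pre`, `switch_rate_pre`) to the richer
#'     (`n_regimes`, `switch_rate`); hippocampal ROI amplitudes are scaled
#'     by `roi_variance_gain`.
#' }
#'
#' @param n_networks number of voxel networks (default 9).
#' @param voxels_per_network voxels per network (default 24).
#' @param n_rois number of regions in the ROI generator (default 4).
#' @param n_timepoints scan length in timepoints (default 240).
#' @param sampling_interval repetition time in seconds (default 3).
#' @param infusion_onset 0-based infusion start (default 120 = midway).
#' @param infusion_duration infusion length in timepoints (default 20 = 60 s).
#' @param condition `"placebo_like"` or `"drug_like"`.
#' @param coupling_sd_post stationary sd of the post-infusion coupling
#'   weight drift in drug-like scans (default 0.5; 0 reproduces the placebo
#'   process).
#' @param n_regimes number of hidden ROI coupling regimes active in the
#'   scan's "drugged" phase (whole scan for placebo-like; default 2).
#' @param switch_rate per-step probability of leaving the current regime
#'   (default 0.05).
#' @param n_regimes_pre,switch_rate_pre baseline regime dynamics used
#'   pre-infusion in drug-like scans (defaults 2 and 0.05).
#' @param noise_sd sd of the additive white measurement noise (default 0.5).
#' @param seed integer root seed; all randomness derives from it.
#' @param network_names names for the voxel networks; length `n_networks`.
#' @param sensory_networks subset of `network_names` whose coupling is never
#'   altered by the drug-like condition (the "sensory-like" null networks).
#' @param region_names names for the ROI set; length `n_rois`.
#' @param gain_regions subset of `region_names` whose post-infusion signal
#'   amplitude is multiplied by `roi_variance_gain` in drug-like scans
#'   (default: the hippocampal pair).
#' @param roi_variance_gain post-infusion amplitude multiplier for
#'   `gain_regions` in drug-like scans (default 1.5, i.e. variance x2.25).
#' @param ar_coef AR(1) coefficient of the latent network signals
#'   (default 0.8, giving a low-frequency, BOLD-like spectrum).
#' @param weight_ar_coef AR(1) coefficient of the coupling-weight drift
#'   (default 0.9: slow relative to the signal).
#' @param coupling_jitter_sd sd of the per-voxel constant baseline coupling
#'   weight around 1 (default 0.1).
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_networks = 9L, voxels_per_network = 24L,
                             n_rois = 4L, n_timepoints = 240L,
                             sampling_interval = 3,
                             infusion_onset = 120L,
                             infusion_duration = 20L,
                             condition = c("placebo_like", "drug_like"),
                             coupling_sd_post = 0.5,
                             n_regimes = 2L, switch_rate = 0.05,
                             n_regimes_pre = 2L, switch_rate_pre = 0.05,
                             noise_sd = 0.5, seed = 1L,
                             network_names = NULL,
                             sensory_networks = NULL,
                             region_names = NULL,
                             gain_regions = NULL,
                             roi_variance_gain = 1.5,
                             ar_coef = 0.8, weight_ar_coef = 0.9,
                             coupling_jitter_sd = 0.1) {
  condition <- match.arg(condition)
  n_networks <- stopifnot_count(n_networks, "n_networks")
  voxels_per_network <- stopifnot_count(voxels_per_network,
                                        "voxels_per_network")
  n_rois <- stopifnot_count(n_rois, "n_rois", min = 2L)
  n_timepoints <- stopifnot_count(n_timepoints, "n_timepoints")
  infusion_onset <- stopifnot_count(infusion_onset, "infusion_onset",
                                    min = 0L)
  infusion_duration <- stopifnot_count(infusion_duration,
                                       "infusion_duration", min = 0L)
  n_regimes <- stopifnot_count(n_regimes, "n_regimes")
  n_regimes_pre <- stopifnot_count(n_regimes_pre, "n_regimes_pre")
  if (infusion_onset + infusion_duration >= n_timepoints)
    stop("invalid config: infusion_onset + infusion_duration must be < ",
         "n_timepoints (", infusion_onset, " + ", infusion_duration,
         " >= ", n_timepoints, ")")
  if (sampling_interval <= 0)
    stop("invalid config: sampling_interval must be > 0")
  if (noise_sd <= 0)
    stop("invalid config: noise_sd must be > 0")
  if (coupling_sd_post < 0)
    stop("invalid config: coupling_sd_post must be >= 0")
  for (r in c(switch_rate = switch_rate, switch_rate_pre = switch_rate_pre))
    if (r < 0 || r > 1)
      stop("invalid config: switch rates must lie in [0, 1]")
  if (abs(ar_coef) >= 1 || abs(weight_ar_coef) >= 1)
    stop("invalid config: AR coefficients must lie in (-1, 1)")
  if (roi_variance_gain <= 0)
    stop("invalid config: roi_variance_gain must be > 0")
  max_regimes <- 2^(n_rois * (n_rois - 1L) / 2)
  if (n_regimes > max_regimes || n_regimes_pre > max_regimes)
    stop("invalid config: at most ", max_regimes,
         " distinct regimes exist for ", n_rois, " regions")

  if (is.null(network_names))
    network_names <- default_network_names(n_networks)
  if (length(network_names) != n_networks)
    stop("invalid config: need ", n_networks, " network names")
  if (is.null(sensory_networks))
    sensory_networks <- intersect(
      c("visual_medial", "visual_occipital", "visual_lateral",
        "sensorimotor", "auditory", "cerebellum"),
      network_names)
  if (!all(sensory_networks %in% network_names))
    stop("invalid config: sensory_networks must be a subset of ",
         "network_names")
  if (is.null(region_names))
    region_names <- default_region_names(n_rois)
  if (length(region_names) != n_rois || anyDuplicated(region_names))
    stop("invalid config: need ", n_rois, " distinct region names")
  if (is.null(gain_regions))
    gain_regions <- grep("hippocampus", region_names, value = TRUE)
  if (!all(gain_regions %in% region_names))
    stop("invalid config: gain_regions must be a subset of region_names")

  structure(
    list(n_networks = n_networks, voxels_per_network = voxels_per_network,
         n_rois = n_rois, n_timepoints = n_timepoints,
         sampling_interval = sampling_interval,
         infusion_onset = infusion_onset,
         infusion_duration = infusion_duration, condition = condition,
         coupling_sd_post = coupling_sd_post, n_regimes = n_regimes,
         switch_rate = switch_rate, n_regimes_pre = n_regimes_pre,
         switch_rate_pre = switch_rate_pre, noise_sd = noise_sd,
         seed = as.integer(seed), network_names = network_names,
         sensory_networks = sensory_networks, region_names = region_names,
         gain_regions = gain_regions,
         roi_variance_gain = roi_variance_gain, ar_coef = ar_coef,
         weight_ar_coef = weight_ar_coef,
         coupling_jitter_sd = coupling_jitter_sd),
    class = "generator_config")
}

default_network_names <- function(n) {
  base <- c("visual_medial", "visual_occipital", "visual_lateral",
            "default_mode", "cerebellum", "sensorimotor", "auditory",
            "executive_control", "frontoparietal")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("network_%02d", seq_len(n - length(base)) +
                         length(base)))
}

default_region_names <- function(n) {
  base <- c("hippocampus_left", "hippocampus_right", "acc_left", "acc_right")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("region_%02d", seq_len(n - length(base)) +
                         length(base)))
}

#' Generate a voxel-level synthetic scan
#'
#' Each network carries a latent unit-variance AR(1) signal; voxel `v` of
#' network `n` emits `w_v(t) * s_n(t) + noise`. Coupling weights `w_v` are
#' constant (drawn once near 1) in placebo-like scans and pre-infusion; in
#' drug-like scans the weights of non-sensory networks acquire, from the
#' infusion onset onward, a slow AR(1) drift with stationary sd
#' `coupling_sd_post`, clipped at zero. That drift lowers voxel-to-network
#' coherence and raises the temporal variance of intra-network synchrony —
#' the metastability signature the downstream analyses measure.
#'
#' @param config a [generator_config()].
#' @return a [voxel_ts_set()] with `config$n_networks * voxels_per_network`
#'   rows.
#' @export
generate_voxel_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_t <- config$n_timepoints
  n_vox <- config$voxels_per_network
  set.seed(derive_seed(config$seed, 1L))
  drugged <- config$condition == "drug_like"
  post_idx <- (config$infusion_onset + 1L):n_t   # onset onward, 1-based
  rows <- vector("list", config$n_networks)
  for (n in seq_len(config$n_networks)) {
    s_n <- ar1_series(n_t, config$ar_coef)
    affected <- drugged &&
      !(config$network_names[n] %in% config$sensory_networks) &&
      config$coupling_sd_post > 0
    net <- matrix(0, nrow = n_vox, ncol = n_t)
    for (v in seq_len(n_vox)) {
      w <- rep(pmax(0, 1 + stats::rnorm(1, sd = config$coupling_jitter_sd)),
               n_t)
      # the drift variates are always drawn so both conditions consume the
      # same random stream: at equal seed, placebo-like data and every
      # unaffected (sensory-like) network are bit-identical across
      # conditions, and coupling_sd_post = 0 reproduces the placebo process
      drift <- ar1_series(length(post_idx), config$weight_ar_coef)
      if (affected)
        w[post_idx] <- pmax(0, w[post_idx] +
                              drift * config$coupling_sd_post)
      net[v, ] <- w * s_n + stats::rnorm(n_t, sd = config$noise_sd)
    }
    rows[[n]] <- net
  }
  voxel_ts_set(do.call(rbind, rows),
               rep(config$network_names, each = n_vox),
               config$sampling_interval,
               infusion_onset = config$infusion_onset,
               infusion_duration = config$infusion_duration,
               condition = config$condition)
}

#' Generate a regime-switching ROI dataset
#'
#' The ROI signals follow a hidden-regime coupled-oscillator model. Each
#' regime is a distinct binary coupling pattern over the region pairs; at
#' any moment the regions form the connected components of the active
#' pattern, and every region in a component shares one common band-limited
#' oscillatory carrier (components are assigned distinct harmonics of a
#' 60-s base period, so carriers of different components are exactly
#' orthogonal over any full-period window). White measurement noise of sd
#' `noise_sd` is added on top, so in the noise-free limit regions of one
#' component are perfectly correlated and regions of different components
#' are exactly uncorrelated within any 20-timepoint window.
#'
#' The hidden regime index follows a Markov chain: it stays put with
#' probability `1 - switch_rate` and otherwise jumps uniformly to another
#' regime. Drug-like scans use baseline dynamics
#' (`n_regimes_pre`, `switch_rate_pre`) before the infusion and the richer
#' (`n_regimes`, `switch_rate`) dynamics from the infusion onset onward;
#' placebo-like scans use (`n_regimes`, `switch_rate`) throughout. In
#' drug-like scans the `gain_regions` amplitudes are multiplied by
#' `roi_variance_gain` post-infusion, planting the regional
#' signal-variance increase.
#'
#' @param config a [generator_config()].
#' @return a [region_ts()]; `$regime_sequence` holds the true hidden regime
#'   index (1-based) per timepoint for validation.
#' @export
generate_roi_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  k <- config$n_rois
  n_t <- config$n_timepoints
  set.seed(derive_seed(config$seed, 2L))
  drugged <- config$condition == "drug_like"
  n_total <- max(config$n_regimes,
                 if (drugged) config$n_regimes_pre else 0L)
  max_code <- 2^(k * (k - 1L) / 2) - 1L
  codes <- sample.int(max_code + 1L, n_total) - 1L  # distinct patterns
  # per-regime component structure and per-component carrier phase
  regimes <- lapply(codes, function(code) {
    comp <- adjacency_components(decode_motif(code, k))
    list(components = comp,
         phases = stats::runif(max(comp), 0, 2 * pi))
  })

  onset <- config$infusion_onset
  regime_seq <- integer(n_t)
  if (drugged) {
    regime_seq[seq_len(onset)] <-
      markov_regimes(onset, config$n_regimes_pre, config$switch_rate_pre)
    post_len <- n_t - onset
    start <- sample.int(config$n_regimes, 1L)
    regime_seq[(onset + 1L):n_t] <-
      markov_regimes(post_len, config$n_regimes, config$switch_rate,
                     start = start)
  } else {
    regime_seq <- markov_regimes(n_t, config$n_regimes, config$switch_rate)
  }

  # carriers: harmonic h of the base period (20 timepoints = 60 s at TR 3)
  base_period <- 20
  tt <- seq_len(n_t) - 1L
  carrier <- function(h, phase) cos(2 * pi * h * tt / base_period + phase)
  data <- matrix(0, nrow = k, ncol = n_t)
  for (t in seq_len(n_t)) {
    reg <- regimes[[regime_seq[t]]]
    for (i in seq_len(k)) {
      c_i <- reg$components[i]
      data[i, t] <- cos(2 * pi * c_i * (t - 1L) / base_period +
                          reg$phases[c_i])
    }
  }
  if (drugged && config$roi_variance_gain != 1) {
    gain_rows <- match(config$gain_regions, config$region_names)
    post_cols <- (onset + 1L):n_t
    data[gain_rows, post_cols] <- data[gain_rows, post_cols] *
      config$roi_variance_gain
  }
  data <- data + matrix(stats::rnorm(k * n_t, sd = config$noise_sd),
                        nrow = k)
  region_ts(data, config$region_names, config$sampling_interval,
            infusion_onset = config$infusion_onset,
            infusion_duration = config$infusion_duration,
            condition = config$condition,
            regime_sequence = regime_seq)
}

# Markov chain over 1..n_regimes: stay w.p. 1 - switch_rate, else jump
# uniformly to one of the other regimes
markov_regimes <- function(n, n_regimes, switch_rate, start = NULL) {
  z <- integer(n)
  if (n == 0L) return(z)
  z[1L] <- if (is.null(start)) sample.int(n_regimes, 1L) else start
  if (n_regimes == 1L) return(rep(1L, n))
  switches <- stats::runif(n) < switch_rate
  for (t in seq_len(n - 1L) + 1L) {
    if (switches[t]) {
      cand <- sample.int(n_regimes - 1L, 1L)
      z[t] <- if (cand >= z[t - 1L]) cand + 1L else cand
    } else z[t] <- z[t - 1L]
  }
  z
}

# connected-component labels (1-based, in order of first appearance) of a
# binary symmetric adjacency matrix
adjacency_components <- function(adj) {
  k <- nrow(adj)
  comp <- integer(k)
  cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        nb <- which(adj[v, ] == 1L & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Generate a matched placebo/drug condition pair for a synthetic cohort
#'
#' Mirrors a within-subject placebo-controlled design: each subject gets one
#' placebo-like and one drug-like scan (voxel-level and ROI-level), built
#' from per-subject seeds derived deterministically from the root seed.
#' The two conditions of a subject differ only in the condition-dependent
#' generator mechanics and in the condition-specific regime parameters.
#'
#' @param config a [generator_config()]; its `condition` field is ignored —
#'   both conditions are generated. Its (`n_regimes`, `switch_rate`)
#'   describe the placebo-like regime dynamics.
#' @param n_subjects number of subjects (default 15).
#' @param drug_overrides named list of config fields overridden in the
#'   drug-like arm only; default `list(n_regimes = 8, switch_rate = 0.2)`,
#'   the richer post-infusion ROI dynamics.
#' @param what which dataset kinds to generate (`"voxel"`, `"roi"`).
#' @return a list of class `condition_pair` with elements `subjects` (a list
#'   of `list(subject_id, placebo = list(voxel, roi), drug = list(voxel,
#'   roi))`) and `config`.
#' @export
generate_condition_pair <- function(config, n_subjects = 15L,
                                    drug_overrides =
                                      list(n_regimes = 8L,
                                           switch_rate = 0.2),
                                    what = c("voxel", "roi")) {
  stopifnot(inherits(config, "generator_config"))
  n_subjects <- stopifnot_count(n_subjects, "n_subjects", min = 2L)
  what <- match.arg(what, several.ok = TRUE)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    per_cond <- function(cond) {
      args <- unclass(config)
      args$condition <- cond
      # separate seed streams per condition: the two arms are scans on
      # different days, so their noise realizations are independent
      args$seed <- derive_seed(config$seed, 100L + s,
                               if (cond == "placebo_like") 1L else 2L)
      if (cond == "drug_like") args[names(drug_overrides)] <- drug_overrides
      cfg <- do.call(generator_config, args)
      out <- list()
      if ("voxel" %in% what) {
        d <- generate_voxel_dataset(cfg)
        d$subject_id <- sprintf("sub-%02d", s)
        out$voxel <- d
      }
      if ("roi" %in% what) {
        d <- generate_roi_dataset(cfg)
        d$subject_id <- sprintf("sub-%02d", s)
        out$roi <- d
      }
      out
    }
    subjects[[s]] <- list(subject_id = sprintf("sub-%02d", s),
                          placebo = per_cond("placebo_like"),
                          drug = per_cond("drug_like"))
  }
  structure(list(subjects = subjects, config = config,
                 drug_overrides = drug_overrides),
            class = "condition_pair")
}
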