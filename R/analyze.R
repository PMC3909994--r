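# Cohort-level drivers: flatten a synthetic (or assembled) condition pair
# into tidy per-subject tables and run the group tests on them. These are
# the functions the analysis scripts and the acceptance checks call.

#' Per-subject network metastability table for a condition pair
#'
#' Runs [network_metastability()] for every subject, condition and network
#' and returns a tidy table.
#'
#' @param pair a `condition_pair` from [generate_condition_pair()] (needs
#'   voxel datasets).
#' @param mode synchrony estimator, `"amplitude"` (default) or `"phase"`.
#' @param band_low_hz,band_high_hz phase-mode pass band.
#' @return data.frame with columns `subject`, `condition`, `network`,
#'   `mode`, `pre`, `post`, `percent_change`.
#' @export
cohort_metastability <- function(pair, mode = c("amplitude", "phase"),
                                 band_low_hz = 0.01, band_high_hz = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "condition_pair"))
  rows <- list()
  for (subj in pair$subjects) {
    for (cond in c("placebo", "drug")) {
      ds <- subj[[cond]]$voxel
      if (is.null(ds)) stop("condition pair has no voxel datasets")
      for (net in unique(ds$network_labels)) {
        m <- network_metastability(ds, net, mode, band_low_hz, band_high_hz)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$subject_id, condition = cond, network = net,
          mode = mode, pre = m$pre_value, post = m$post_value,
          percent_change = m$percent_change)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-subject network synchrony-entropy table for a condition pair
#'
#' Runs [network_entropy()] (pre/post binned distributions on a pooled
#' support, Shannon entropy, entropy change) for every subject, condition
#' and network.
#'
#' @inheritParams cohort_metastability
#' @param n_bins,edges_strategy passed to [network_entropy()].
#' @return data.frame with columns `subject`, `condition`, `network`,
#'   `mode`, `h_pre`, `h_post`, `delta_h`.
#' @export
cohort_entropy <- function(pair, mode = c("amplitude", "phase"),
                           n_bins = 10L, edges_strategy = "pooled",
                           band_low_hz = 0.01, band_high_hz = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "condition_pair"))
  rows <- list()
  for (subj in pair$subjects) {
    for (cond in c("placebo", "drug")) {
      ds <- subj[[cond]]$voxel
      if (is.null(ds)) stop("condition pair has no voxel datasets")
      for (net in unique(ds$network_labels)) {
        e <- network_entropy(ds, net, mode, n_bins, edges_strategy,
                             band_low_hz, band_high_hz)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$subject_id, condition = cond, network = net,
          mode = mode, h_pre = e$h_pre, h_post = e$h_post,
          delta_h = e$delta_h)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-subject motif statistics for a condition pair
#'
#' Builds motif sequences over matched-length pre- and post-infusion
#' segments of each subject's ROI series (the pre segment is the
#' `post`-length window ending at the infusion onset, so pre/post and
#' placebo/drug entropies are compared at equal sequence length) and
#' tabulates repertoire size and order-0/order-1 motif-sequence entropy.
#'
#' @inheritParams cohort_metastability
#' @param window_len,step,threshold,use_absolute motif-pipeline parameters
#'   (see [motif_sequence()]).
#' @return data.frame with columns `subject`, `condition`, `phase`
#'   (`"pre"`/`"post"`), `n_windows`, `repertoire`, `h0`, `h1`.
#' @export
cohort_motifs <- function(pair, window_len = 20L, step = 1L,
                          threshold = 0.5, use_absolute = FALSE) {
  stopifnot(inherits(pair, "condition_pair"))
  rows <- list()
  for (subj in pair$subjects) {
    for (cond in c("placebo", "drug")) {
      ds <- subj[[cond]]$roi
      if (is.null(ds)) stop("condition pair has no ROI datasets")
      post <- post_segment(ds)
      pre_len <- segment_length(post)
      pre <- segment(ds$infusion_onset - pre_len, ds$infusion_onset)
      for (ph in c("pre", "post")) {
        sq <- suppressMessages(
          motif_sequence(ds, window_len, step, threshold, use_absolute,
                         seg = if (ph == "pre") pre else post))
        rep_ <- motif_repertoire(sq)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$subject_id, condition = cond, phase = ph,
          n_windows = length(sq$codes), repertoire = rep_$n_distinct,
          h0 = motif_entropy(sq, 0L), h1 = motif_entropy(sq, 1L))
      }
    }
  }
  do.call(rbind, rows)
}

#' Group tests of metastability percent change against zero
#'
#' One two-tailed one-sample t-test per condition and network, comparing
#' the per-subject percent changes against zero at the Bonferroni-corrected
#' threshold `alpha_family / n_networks`.
#'
#' @param metastab per-subject table from [cohort_metastability()].
#' @param alpha_family family-wise alpha (default 0.05).
#' @return data.frame with one row per condition x network: `condition`,
#'   `network`, `mode`, `mean_change`, `t`, `p`, `n`, `alpha_corrected`,
#'   `significant`.
#' @export
group_metastability_tests <- function(metastab, alpha_family = 0.05) {
  nets <- unique(metastab$network)
  thr <- bonferroni_threshold(alpha_family, length(nets))$threshold
  rows <- list()
  for (cond in unique(metastab$condition)) {
    for (net in nets) {
      v <- metastab$percent_change[metastab$condition == cond &
                                     metastab$network == net]
      tr <- one_sample_t(v, 0, thr, measure = paste(cond, net, sep = ":"))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, network = net, mode = metastab$mode[1L],
        mean_change = tr$estimate, t = tr$t, p = tr$p, n = tr$n,
        alpha_corrected = thr, significant = tr$significant)
    }
  }
  do.call(rbind, rows)
}

#' Drug-vs-placebo contrast of per-subject entropy changes
#'
#' Per network, a paired two-tailed t-test of the per-subject entropy change
#' under drug vs. under placebo, at `alpha_family / n_networks`.
#'
#' @param entropy per-subject table from [cohort_entropy()].
#' @param alpha_family family-wise alpha.
#' @return data.frame with one row per network: `network`, `mode`,
#'   `mean_delta_drug`, `mean_delta_placebo`, `t`, `p`, `n`,
#'   `alpha_corrected`, `significant`.
#' @export
group_entropy_contrast <- function(entropy, alpha_family = 0.05) {
  nets <- unique(entropy$network)
  thr <- bonferroni_threshold(alpha_family, length(nets))$threshold
  rows <- list()
  for (net in nets) {
    sub <- entropy[entropy$network == net, ]
    wide <- merge(sub[sub$condition == "drug",
                      c("subject", "delta_h")],
                  sub[sub$condition == "placebo",
                      c("subject", "delta_h")],
                  by = "subject", suffixes = c("_drug", "_placebo"))
    tr <- condition_contrast(wide$delta_h_drug, wide$delta_h_placebo,
                             paired = TRUE, alpha_corrected = thr,
                             measure = net)
    rows[[length(rows) + 1L]] <- data.frame(
      network = net, mode = entropy$mode[1L],
      mean_delta_drug = mean(wide$delta_h_drug),
      mean_delta_placebo = mean(wide$delta_h_placebo),
      t = tr$t, p = tr$p, n = tr$n, alpha_corrected = thr,
      significant = tr$significant)
  }
  do.call(rbind, rows)
}

#' Drug-vs-placebo contrast of motif statistics
#'
#' Paired contrasts of the post-infusion motif repertoire size and
#' motif-sequence entropy (order 0 and 1) between the two arms.
#'
#' @param motifs per-subject table from [cohort_motifs()].
#' @param alpha single-test alpha (default 0.05).
#' @return data.frame with one row per statistic: `statistic`,
#'   `mean_drug`, `mean_placebo`, `t`, `p`, `n`, `significant`.
#' @export
group_motif_contrast <- function(motifs, alpha = 0.05) {
  post <- motifs[motifs$phase == "post", ]
  wide <- merge(post[post$condition == "drug", ],
                post[post$condition == "placebo", ],
                by = "subject", suffixes = c("_drug", "_placebo"))
  rows <- list()
  for (stat in c("repertoire", "h0", "h1")) {
    d <- wide[[paste0(stat, "_drug")]]
    p <- wide[[paste0(stat, "_placebo")]]
    tr <- condition_contrast(d, p, paired = TRUE, alpha_corrected = alpha,
                             measure = stat)
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = stat, mean_drug = mean(d), mean_placebo = mean(p),
      t = tr$t, p = tr$p, n = tr$n, significant = tr$significant)
  }
  do.call(rbind, rows)
}
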