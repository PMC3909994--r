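# Declarative pipeline runner: a single YAML config describes the synthetic
# cohort and every analysis parameter; run_pipeline() executes the stages
# generate -> synchrony -> entropy -> motifs -> report, writes tidy TSVs and
# a JSON manifest (config snapshot, seed, package version), and is
# deterministic given the config.

config_schema <- function() {
  list(
    seed = list(check = function(x) is.numeric(x) && x == round(x),
                msg = "an integer"),
    generator = list(
      n_networks = list(check = function(x) is_count(x), msg = "a count >= 1"),
      voxels_per_network = list(check = function(x) is_count(x),
                                msg = "a count >= 1"),
      n_rois = list(check = function(x) is_count(x, 2), msg = "a count >= 2"),
      n_timepoints = list(check = function(x) is_count(x),
                          msg = "a count >= 1"),
      sampling_interval = list(check = function(x) is.numeric(x) && x > 0,
                               msg = "a positive number (seconds)"),
      infusion_onset = list(check = function(x) is_count(x, 0),
                            msg = "a timepoint index >= 0"),
      infusion_duration = list(check = function(x) is_count(x, 0),
                               msg = "a count >= 0"),
      coupling_sd_post = list(check = function(x) is.numeric(x) && x >= 0,
                              msg = "a number >= 0"),
      n_regimes = list(check = function(x) is_count(x), msg = "a count >= 1"),
      switch_rate = list(check = function(x) is.numeric(x) && x >= 0 &&
                           x <= 1, msg = "a probability in [0, 1]"),
      noise_sd = list(check = function(x) is.numeric(x) && x > 0,
                      msg = "a number > 0"),
      roi_variance_gain = list(check = function(x) is.numeric(x) && x > 0,
                               msg = "a number > 0")),
    cohort = list(
      n_subjects = list(check = function(x) is_count(x, 2),
                        msg = "a count >= 2"),
      drug_n_regimes = list(check = function(x) is_count(x),
                            msg = "a count >= 1"),
      drug_switch_rate = list(check = function(x) is.numeric(x) && x >= 0 &&
                                x <= 1, msg = "a probability in [0, 1]")),
    synchrony = list(
      mode = list(check = function(x) x %in% c("phase", "amplitude"),
                  msg = "'phase' or 'amplitude'"),
      band_low_hz = list(check = function(x) is.numeric(x) && x > 0,
                         msg = "a frequency > 0"),
      band_high_hz = list(check = function(x) is.numeric(x) && x > 0,
                          msg = "a frequency > 0")),
    entropy = list(
      n_bins = list(check = function(x) is_count(x, 2), msg = "a count >= 2"),
      edges_strategy = list(check = function(x)
        x %in% c("pooled", "centered"), msg = "'pooled' or 'centered'")),
    motifs = list(
      window_len = list(check = function(x) is_count(x, 3),
                        msg = "a count >= 3"),
      step = list(check = function(x) is_count(x), msg = "a count >= 1"),
      threshold = list(check = function(x) is.numeric(x) && x > -1 && x < 1,
                       msg = "a correlation in (-1, 1)"),
      use_absolute = list(check = is.logical, msg = "true or false")),
    group = list(
      alpha = list(check = function(x) is.numeric(x) && x > 0 && x < 1,
                   msg = "an alpha in (0, 1)")))
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x >= min
}

#' Default pipeline configuration
#'
#' The full nested parameter list understood by [run_pipeline()] /
#' [validate_config()], at its defaults: a 15-subject synthetic cohort at
#' the default scan geometry, amplitude-mode (dispersion) synchrony, 10
#' equal-width pooled bins, and the 20-timepoint / step-1 / 0.5-threshold
#' motif pipeline.
#'
#' @return a nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    generator = list(n_networks = 9L, voxels_per_network = 24L,
                     n_rois = 4L, n_timepoints = 240L,
                     sampling_interval = 3, infusion_onset = 120L,
                     infusion_duration = 20L, coupling_sd_post = 0.5,
                     n_regimes = 2L, switch_rate = 0.05, noise_sd = 0.5,
                     roi_variance_gain = 1.5),
    cohort = list(n_subjects = 15L, drug_n_regimes = 8L,
                  drug_switch_rate = 0.2),
    synchrony = list(mode = "amplitude", band_low_hz = 0.01,
                     band_high_hz = 0.1),
    entropy = list(n_bins = 10L, edges_strategy = "pooled"),
    motifs = list(window_len = 20L, step = 1L, threshold = 0.5,
                  use_absolute = FALSE),
    group = list(alpha = 0.05))
}

#' Validate a pipeline configuration
#'
#' Type- and range-checks every key of a config (a YAML file path or a
#' nested list) against the documented schema, with no side effects.
#' Unknown keys are reported with a nearest-known-key suggestion.
#'
#' @param config path to a YAML config file, or a nested list.
#' @return character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  schema <- config_schema()
  violations <- character()
  suggest <- function(key, known) {
    d <- utils::adist(key, known)
    paste0(" (did you mean '", known[which.min(d)], "'?)")
  }
  top_known <- names(schema)
  for (key in names(config)) {
    if (!key %in% top_known) {
      violations <- c(violations,
                      paste0("unknown section '", key, "'",
                             suggest(key, top_known)))
      next
    }
    if (key == "seed") {
      if (!schema$seed$check(config$seed))
        violations <- c(violations, "seed must be an integer")
      next
    }
    section <- schema[[key]]
    for (sub in names(config[[key]])) {
      if (!sub %in% names(section)) {
        violations <- c(violations,
                        paste0("unknown key '", key, ".", sub, "'",
                               suggest(sub, names(section))))
        next
      }
      val <- config[[key]][[sub]]
      if (!isTRUE(section[[sub]]$check(val)))
        violations <- c(violations,
                        paste0(key, ".", sub, " must be ",
                               section[[sub]]$msg, " (got '",
                               paste(val, collapse = ","), "')"))
    }
  }
  g <- merge_config(default_config(), config)
  if (length(violations) == 0L &&
      g$generator$infusion_onset + g$generator$infusion_duration >=
        g$generator$n_timepoints)
    violations <- c(violations,
                    "generator: infusion window must end before the last timepoint")
  if (length(violations) == 0L &&
      g$synchrony$band_low_hz >= g$synchrony$band_high_hz)
    violations <- c(violations,
                    "synchrony: band_low_hz must be < band_high_hz")
  violations
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]]))
      base[[key]] <- merge_config(base[[key]], override[[key]])
    else base[[key]] <- override[[key]]
  }
  base
}

#' Run the full analysis pipeline from a config
#'
#' Executes the requested stages in order — `generate` (synthetic condition
#' pair), `synchrony` (per-subject metastability table), `entropy`
#' (per-subject synchrony-entropy table), `motifs` (per-subject motif
#' table), `report` (group tests and a human-readable summary) — writing
#' each table as a TSV under `out_dir` plus a `manifest.json` recording the
#' merged config, seed, package version and outputs. Later stages need the
#' generated cohort, so `generate` is always implied. Validation failures
#' abort before any stage runs.
#'
#' @param config YAML config path or nested list; unset keys fall back to
#'   [default_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("generate", "synchrony", "entropy", "motifs", "report")`.
#' @return invisibly, the manifest list; side effect: TSV/JSON files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = c("generate", "synchrony", "entropy",
                                    "motifs", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config)) {
    viol <- validate_config(config)
    config <- yaml::read_yaml(config)
  } else viol <- validate_config(config)
  if (length(viol))
    stop("invalid config:\n  - ", paste(viol, collapse = "\n  - "))
  cfg <- merge_config(default_config(), config)
  cfg$seed <- as.integer(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs <<- c(outputs, path)
    message("[", name, "] wrote ", path, " (", nrow(df), " rows)")
  }

  message("[generate] cohort of ", cfg$cohort$n_subjects,
          " subjects, seed ", cfg$seed)
  gen <- cfg$generator
  base_cfg <- generator_config(
    n_networks = gen$n_networks,
    voxels_per_network = gen$voxels_per_network, n_rois = gen$n_rois,
    n_timepoints = gen$n_timepoints,
    sampling_interval = gen$sampling_interval,
    infusion_onset = gen$infusion_onset,
    infusion_duration = gen$infusion_duration,
    coupling_sd_post = gen$coupling_sd_post, n_regimes = gen$n_regimes,
    switch_rate = gen$switch_rate, noise_sd = gen$noise_sd,
    roi_variance_gain = gen$roi_variance_gain, seed = cfg$seed)
  pair <- generate_condition_pair(
    base_cfg, cfg$cohort$n_subjects,
    drug_overrides = list(n_regimes = cfg$cohort$drug_n_regimes,
                          switch_rate = cfg$cohort$drug_switch_rate))

  metastab <- entropy_tab <- motif_tab <- NULL
  if ("synchrony" %in% stages) {
    message("[synchrony] mode ", cfg$synchrony$mode)
    metastab <- cohort_metastability(pair, cfg$synchrony$mode,
                                     cfg$synchrony$band_low_hz,
                                     cfg$synchrony$band_high_hz)
    emit(metastab, "metastability")
  }
  if ("entropy" %in% stages) {
    message("[entropy] ", cfg$entropy$n_bins, " bins, ",
            cfg$entropy$edges_strategy, " edges")
    entropy_tab <- cohort_entropy(pair, cfg$synchrony$mode,
                                  cfg$entropy$n_bins,
                                  cfg$entropy$edges_strategy,
                                  cfg$synchrony$band_low_hz,
                                  cfg$synchrony$band_high_hz)
    emit(entropy_tab, "entropy")
  }
  if ("motifs" %in% stages) {
    message("[motifs] window ", cfg$motifs$window_len, ", step ",
            cfg$motifs$step, ", threshold ", cfg$motifs$threshold)
    motif_tab <- cohort_motifs(pair, cfg$motifs$window_len,
                               cfg$motifs$step, cfg$motifs$threshold,
                               cfg$motifs$use_absolute)
    emit(motif_tab, "motifs")
  }
  if ("report" %in% stages) {
    for (need in c("synchrony", "entropy", "motifs"))
      if (!need %in% stages)
        stop("stage 'report' needs upstream stage '", need, "'")
    message("[report] group inference, alpha ", cfg$group$alpha)
    tests <- group_metastability_tests(metastab, cfg$group$alpha)
    contrast <- group_entropy_contrast(entropy_tab, cfg$group$alpha)
    motif_con <- group_motif_contrast(motif_tab, cfg$group$alpha)
    emit(tests, "report_metastability_tests")
    emit(contrast, "report_entropy_contrast")
    emit(motif_con, "report_motif_contrast")
    writeLines(report_summary(cfg, tests, contrast, motif_con),
               file.path(out_dir, "summary.txt"))
    outputs <- c(outputs, file.path(out_dir, "summary.txt"))
  }

  manifest <- list(package = "dynent",
                   version = as.character(utils::packageVersion("dynent")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE),
                   seed = cfg$seed, stages = stages, config = cfg,
                   outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

report_summary <- function(cfg, tests, contrast, motif_con) {
  thr <- bonferroni_threshold(cfg$group$alpha,
                              length(unique(tests$network)))
  drug <- tests[tests$condition == "drug", ]
  c(sprintf("dynent pipeline summary (seed %d, %d subjects, mode %s)",
            cfg$seed, cfg$cohort$n_subjects, cfg$synchrony$mode),
    sprintf("Bonferroni-corrected threshold: p < %.3f (%.2f/%d)",
            thr$display, cfg$group$alpha, length(unique(tests$network))),
    "",
    "Metastability percent change (drug arm), one-sample t vs 0:",
    sprintf("  %-18s mean %+7.1f%%  t = %+6.2f  p = %-8.3g %s",
            drug$network, drug$mean_change, drug$t, drug$p,
            ifelse(drug$significant, "*", "")),
    "",
    "Entropy-change contrast (drug vs placebo, paired):",
    sprintf("  %-18s dH(drug) %+6.3f  dH(placebo) %+6.3f  p = %-8.3g %s",
            contrast$network, contrast$mean_delta_drug,
            contrast$mean_delta_placebo, contrast$p,
            ifelse(contrast$significant, "*", "")),
    "",
    "Motif contrasts (post-infusion, drug vs placebo, paired):",
    sprintf("  %-10s drug %7.3f  placebo %7.3f  p = %-8.3g %s",
            motif_con$statistic, motif_con$mean_drug,
            motif_con$mean_placebo, motif_con$p,
            ifelse(motif_con$significant, "*", "")))
}
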