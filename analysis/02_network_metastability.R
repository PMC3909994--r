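#!/usr/bin/env Rscript
# Network metastability: the temporal variance of intra-network synchrony,
# pre vs post infusion, per subject and condition, with one-sample t-tests
# of the percent change against zero at the Bonferroni-corrected threshold
# 0.05/9. Reported in the default amplitude (dispersion) mode and in phase
# (Kuramoto) mode.

library(dynent)

out <- "results"
dir.create(out, showWarnings = FALSE)
pair <- generate_condition_pair(generator_config(seed = 1),
                                n_subjects = 15)

for (mode in c("amplitude", "phase")) {
  ms <- cohort_metastability(pair, mode)
  tests <- group_metastability_tests(ms, alpha_family = 0.05)
  write.table(ms, file.path(out, paste0("metastability_", mode, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(tests,
              file.path(out, paste0("metastability_tests_", mode, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  drug <- tests[tests$condition == "drug", ]
  sig <- drug$network[drug$significant]
  cat("\n[", mode, " mode] drug arm, threshold p < ",
      bonferroni_threshold(0.05, 9)$display, ":\n", sep = "")
  for (i in seq_len(nrow(drug)))
    cat(sprintf("  %-18s %+8.1f%%  p = %-9.3g%s\n", drug$network[i],
                drug$mean_change[i], drug$p[i],
                if (drug$significant[i]) " *" else ""))
  cat("  significant networks:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  cat("  placebo arm significant:",
      sum(tests$significant[tests$condition == "placebo"]), "of 9\n")
}
cat("\nWrote results/metastability_{amplitude,phase}.tsv and test tables.\n")
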