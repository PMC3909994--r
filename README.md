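# dynent: entropy and metastability of dynamic brain network states

`dynent` implements a family of entropy-based descriptors of resting-state
brain dynamics for placebo-controlled infusion designs, in which a drug is
infused midway through a scan and the question is whether cortical dynamics
become more variable — "more entropic" — afterwards. It is written for
researchers analyzing voxel-level or ROI-level BOLD time series (or any
labeled multichannel recording) who want the full chain from raw matrices
to group inference, plus a synthetic-data generator that makes every stage
of that chain testable end to end without access to raw imaging data.

## What it computes

**Intra-network synchrony and metastability.** For each labeled network,
a per-timepoint synchrony trace by either of two estimators:

- *amplitude mode* (default): voxels are z-scored and the trace is the
  cross-voxel dispersion around the network mean,
  `d(t) = sqrt(mean_v (z_v(t) − z̄(t))²)` — low dispersion means the
  network mean is a good model of its voxels;
- *phase mode*: voxels are band-pass filtered (0.01–0.1 Hz), converted to
  analytic signals, and summarized by the Kuramoto order parameter
  `R(t) = |N⁻¹ Σ_v exp(iθ_v(t))| ∈ [0, 1]`.

Metastability is the temporal variance of the synchrony trace over a
segment; the analysis contrasts the pre-infusion segment `[0, onset)` with
the post-infusion segment `[onset + duration, end)` as a percent change.

**Shannon entropy of synchrony distributions.** Each trace segment is
discretized into equal-width bins on a support pooled across the pre/post
pair, and `H = −Σ p_i log₂ p_i` (bits) is compared pre vs post and between
conditions.

**Connectivity-motif repertoire and sequence entropy.** For a small ROI set
(default: bilateral hippocampus and anterior cingulate, k = 4),
sliding-window Pearson correlations are thresholded into binary graphs and
encoded bijectively as integer motif codes — `2^(k(k−1)/2)` possible motifs,
64 for four nodes. The package reports repertoire size, condition-exclusive
motifs, and the entropy of the motif sequence (order 0: motif frequencies,
like word frequencies in a passage of text; order 1: conditional on the
previous motif).

**Group inference.** Two-tailed one-sample t-tests of percent changes
against zero, paired drug-vs-placebo contrasts of entropy changes, and
rating-item correlation screens, all at Bonferroni-corrected thresholds
(0.05/9 tests displays as p < 0.006; 0.05/23 as p < 0.002).

**Synthetic cohort generator.** `generator_config()` /
`generate_condition_pair()` emulate the design: 12-min scans at TR 3 s
(240 timepoints) with a 60-s infusion from timepoint 120, nine labeled
networks whose voxels share latent AR(1) signals, and a regime-switching
ROI set. The drug-like condition makes voxel-to-network coupling drift
post-infusion in association-like networks only, and enriches the hidden
connectivity-regime dynamics — so the pipeline's job is to recover a known,
planted dissociation.

## Worked example

```r
library(dynent)
pair <- generate_condition_pair(generator_config(seed = 1), n_subjects = 15)
ms    <- cohort_metastability(pair)          # amplitude mode by default
tests <- group_metastability_tests(ms, alpha_family = 0.05)
subset(tests, condition == "drug",
       select = c(network, mean_change, p, significant))
```

```
             network mean_change            p significant
10     visual_medial       -2.54 4.343477e-01       FALSE
13      default_mode      473.02 4.050424e-07        TRUE
17 executive_control      541.42 3.485988e-09        TRUE
18    frontoparietal      510.33 1.395273e-07        TRUE
...
```

Post-infusion metastability rises by roughly +500 % in the three
association-like networks (significant at the corrected threshold
p < 0.006 = 0.05/9) and stays flat in the six sensory-like networks; in
the placebo arm nothing crosses the threshold. The same cohort shows a
mean entropy gain of about +1.0 bits in affected networks under the drug
analog versus ~0.0 under placebo, a post-infusion motif repertoire of
11.8 vs 7.5 distinct motifs, and motif-sequence entropy of 2.62 vs 1.81
bits (paired p < 0.01) — the planted condition difference, recovered.

The numbered scripts under `analysis/` run the full study in order
(simulation, metastability, entropy, motifs, secondary analyses, and a
config-driven pipeline demo) and write their tables under `results/`.
`run_pipeline()` executes the same stages from a single YAML config (see
`inst/extdata/demo_config.yaml`) and leaves a manifest recording the seed,
config snapshot and package version beside the outputs.

Real data enter through `read_matrix_dataset()` (TSV matrix + label
sidecar + metadata file) or `read_nifti_dataset()` (4D NIfTI plus an
integer network-label volume).

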