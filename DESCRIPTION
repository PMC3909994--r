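Package: dynent
Title: Entropy and Metastability of Dynamic Brain Network States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyses of dynamic brain-state entropy for pre/post
    drug-infusion resting-state designs: intra-network synchrony traces
    (Kuramoto phase order parameter or amplitude dispersion), network
    metastability as the temporal variance of synchrony, Shannon entropy of
    binned synchrony distributions, time-resolved four-node connectivity
    motifs with motif-repertoire and motif-sequence entropy, and group-level
    inference (one-sample and paired t-tests with Bonferroni correction,
    rating-item correlations). Includes a synthetic BOLD-like generator that
    emulates a placebo-controlled infusion design with labeled resting-state
    networks and regime-switching regional connectivity, so every stage of
    the pipeline can be validated end to end without access to raw imaging
    data. Reads delimited time-series bundles and NIfTI-1 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
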