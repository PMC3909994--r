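---
title: "Entropy-based descriptors of brain-state dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based descriptors of brain-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynent` quantifies how "entropic" resting-state brain dynamics are, and
how that changes when a drug is infused midway through a scan. This
vignette is the package's account of the underlying models: what each
statistic assumes, which knobs matter, what the synthetic generator does
and does not emulate, and where we made judgment calls.

## The design being analyzed

The target design is within-subject and placebo-controlled: each subject
is scanned twice (different days), each scan lasts 12 minutes, and an
intravenous infusion begins midway and lasts 60 s. At the default
repetition time of 3 s this gives 240 timepoints with the infusion
occupying `[120, 140)` (all indexing in the package is 0-based,
half-open). The infusion minute is a pharmacological transition, and the
analyses exclude it from both segments: *pre* is `[0, 120)` and *post* is
`[140, 240)`. The repetition time is configurable; 3 s is a typical value
for whole-brain BOLD coverage.

Voxels carry one of nine network labels (the conventional resting-state
decomposition into visual, sensorimotor, auditory, cerebellar,
default-mode, executive-control and frontoparietal systems); users of real
data supply their own label volume or sidecar.

## Intra-network synchrony: two estimators

"Synchrony of a network's voxels" is not a single mathematical object, so
the package implements two readings and reports results per mode.

**Amplitude mode (default).** Z-score every voxel over the scan and take,
at each timepoint, the population standard deviation across voxels of the
deviations from the network-mean z-value:
$$d(t) = \sqrt{\tfrac{1}{N}\sum_v \big(z_v(t) - \bar z(t)\big)^2}.$$
If the network mean is a good model of its voxels, $d(t)$ is small. This
is the dispersion reading: higher values mean *less* synchrony. It uses
the raw (z-scored) amplitudes, makes no spectral assumptions, and is valid
over the whole scan.

**Phase mode.** Linearly detrend each voxel, band-pass 0.01–0.1 Hz (the
conventional resting-state band), form the analytic signal, and compute
the Kuramoto order parameter of the instantaneous phases,
$R(t) = |N^{-1}\sum_v e^{i\theta_v(t)}| \in [0,1]$. The band-pass and the
analytic signal are computed in a single frequency-domain pass (brick-wall
mask; negative frequencies zeroed, in-band positive frequencies doubled),
which is exactly zero-phase. Because the mask is applied circularly, the
record ends carry wrap-around transients: the first and last 10 timepoints
(30 s) are marked invalid and excluded from all downstream segments.

**Why amplitude is the default.** The two estimators answer slightly
different questions, and for the pre/post *percent change* analysis they
behave differently as statistics. The temporal variance of $R(t)$ in this
band is estimated from few effective degrees of freedom per segment, so
the ratio `(post − pre)/pre` inherits a substantial positive small-sample
bias under stationarity and a large dispersion; calibration runs on the
package's own stationary placebo process (200 simulated scans) put that
bias near +11% with a standard deviation of ~53%, while the dispersion
estimator's percent change centers near +1% with a standard deviation of
~18%. The dispersion estimator also responds directly to the
coupling-weight drift that the drug-like generator plants, whereas the
phase estimator registers amplitude fading only indirectly. Both remain
available everywhere via `mode = "phase"` / `"amplitude"`, and neither is
claimed to reproduce any particular published quantity numerically.

**Metastability** is the unbiased (n − 1) sample variance of the
synchrony trace over a segment, and the headline per-network statistic is
its percent change, `(post − pre)/pre × 100`, which requires a strictly
positive baseline (a zero baseline raises an error rather than returning
an infinity).

## Entropy of binned synchrony distributions

Each segment of a synchrony trace is discretized into `n_bins` equal-width
bins (default 10 — at 240 timepoints this leaves on the order of 10–24
samples per bin, enough for a stable plug-in estimate without flattening
the distribution). Bins are right-open except the last; probabilities are
relative frequencies; entropy is $H=-\sum_i p_i\log_2 p_i$ in bits with
$0\log 0 = 0$, so $0 \le H \le \log_2 n_{\text{bins}}$. Bits (base 2) are
used throughout for comparability with the 4-node motif ceiling of
$\log_2 64 = 6$ bits.

Three edge-placement strategies exist:

- `"pooled"` (default): edges span the combined range of the pre and post
  segments of that subject–network pair, so the two distributions share a
  support and their difference $\Delta H = H_{\text{post}} -
  H_{\text{pre}}$ is meaningful. `entropy_change()` refuses distributions
  built on different edges.
- `"fixed"`: user-specified range, for cross-subject comparability.
- `"centered"`: equal-width bins on the absolute deviation from the pooled
  mean — the "distance from the mean" reading of binning; provided as an
  alternative interpretation of how equal bins may be laid out.

"Equal-sized bins" could also mean equal-count (quantile) bins; we chose
equal *width*, since quantile binning forces every segment toward the
uniform distribution and thereby erases exactly the entropy differences
the analysis is after. A degenerate segment (all values identical)
returns a single-occupied-bin distribution with a warning rather than an
error, so that downstream entropy is a well-defined 0. The plug-in
estimator is biased low in small samples; an optional Miller–Madow
correction (`correction = "miller_madow"`) adds $(m-1)/(2n\ln 2)$ but is
off by default, keeping the headline numbers plain plug-in estimates.

## Connectivity motifs over a small ROI set

For k labeled regions (default 4: left/right hippocampus, left/right
anterior cingulate), connectivity is time-resolved by sliding-window
Pearson correlation: window length 20 timepoints (60 s at TR 3 s — long
enough for a usable correlation estimate, short enough to track regime
switches), step 1, both configurable and recorded in outputs. A window
containing a constant region is dropped and counted. Each window's
correlation matrix is thresholded — an edge exists where $c_{ij} > 0.5$
(signed, by default; absolute-value thresholding is available) — and the
resulting binary graph is encoded as an integer: node pairs are ordered
lexicographically `(0,1), (0,2), ..., (k−2,k−1)` and pair b contributes
$2^b$. The encoding is bijective, and the motif space has size
$2^{k(k-1)/2}$ — 64 for four nodes, a count that includes the empty graph
(the only reading consistent with 64). Labeled graphs are deliberately
*not* collapsed to isomorphism classes.

The motif analysis reports repertoire size (distinct motifs), per-motif
frequencies, motifs exclusive to one condition, and motif-sequence
entropy: order 0 is the plug-in entropy of motif frequencies (the
word-frequency analogy: how uneven is the vocabulary), order 1 the
conditional entropy of the next motif given the current one (how
predictable are the transitions). Conditioning can only reduce entropy,
so order 1 ≤ order 0 — an invariant the test suite checks on random
sequences. Entropy comparisons between conditions are made at matched
sequence lengths: the pre segment used for motifs is the post-length
window ending at the infusion onset. The default threshold of 0.5 is not
privileged; the motif analysis script sweeps {0.3, 0.4, 0.5, 0.6} so
conclusions can be shown threshold-robust. Sliding-window correlation is
our reading of "a connectivity graph at each time point"; instantaneous
phase-coherence graphs would be an alternative.

## Group inference

Per-network percent changes are tested against zero with classical
two-tailed one-sample t-tests (n − 1 df); with nine networks the
family-wise level 0.05 gives the Bonferroni per-test threshold 0.05/9,
displayed as p < 0.006 (display rounding to 3 decimals is a reporting
convention only; decisions use full precision). The drug-vs-placebo
entropy contrast is a *paired* t-test on per-subject
$\Delta H_{\text{drug}} - \Delta H_{\text{placebo}}$ — paired because the
design is within-subject, even though that is an assumption about the
original analyses rather than a stated fact. The rating screen correlates
one per-subject neural change score against m rating items (two-tailed
Pearson, threshold 0.05/m; with 23 items, p < 0.002), reporting r, r² and
the significance flag per item; a constant item yields NA for that item
only. Identical paired vectors return t = 0, p = 1 (no evidence) rather
than an error; a constant nonzero difference is degenerate and raises one.

## The synthetic generator: what it emulates, and what it does not

The generator exists so every stage has a ground truth. Each network n has
a latent unit-variance AR(1) signal $s_n(t)$ with coefficient 0.8, giving
the low-frequency, autocorrelated character of BOLD without claiming a
hemodynamic model. Voxel v emits $x_v(t) = w_v(t)\,s_n(t) + \varepsilon$,
$\varepsilon$ white with sd `noise_sd` (default 0.5). Coupling weights
$w_v$ are drawn once near 1 (jitter sd 0.1) and stay constant — except in
the drug-like condition, where from the infusion onset onward the weights
of the three association-like networks (default-mode, executive-control,
frontoparietal) acquire a slow AR(1) drift (coefficient 0.9) with
stationary sd `coupling_sd_post` (default 0.5), clipped at zero. Drifting
weights decouple voxels from their network signal intermittently, which
raises the dispersion trace's variance — the planted metastability
signature. The six sensory-like networks are never perturbed and serve as
built-in null networks. Both conditions consume identical random streams,
so at equal seed the placebo scan and every unperturbed network are
bit-identical across conditions, and `coupling_sd_post = 0` reproduces
the placebo process exactly — properties the test suite asserts
structurally.

The ROI generator is a hidden-regime coupled-oscillator model: each regime
is a distinct binary coupling pattern over the region pairs; at any moment
the regions of one connected component share a common oscillatory carrier
(components are assigned distinct harmonics of a 60-s base period, so
different components are exactly orthogonal over any full-period window),
plus white noise. The regime index follows a Markov chain (stay
probability 1 − `switch_rate`, uniform jumps otherwise). Placebo-like
scans use (`n_regimes` = 2, `switch_rate` = 0.05) throughout; drug-like
scans switch from those baseline dynamics to a richer post-infusion set
(8 regimes, rate 0.2 in the cohort default). In the noise-free limit a
single frozen regime therefore yields exactly one motif for any seed —
the degenerate anchor the acceptance checks use. Drug-like scans also
scale the hippocampal amplitudes by 1.5 post-infusion (variance × 2.25),
planting the regional variance increase. The true regime sequence is
returned alongside the signals for validation.

Deliberately *not* modeled: hemodynamic convolution (the latent signals
are already band-limited), physiological noise and motion, spatial
structure within networks, inter-network coupling (so between-network
correlation is a null readout on synthetic data), receptor pharmacology,
and electrophysiology. Passing tests on this generator demonstrates that
the estimators recover the statistical structure they target — not that
real psychedelic data contain that structure.

## Numerical conventions and problem sizes

- Seeds: one root seed, expanded into per-subject, per-condition,
  per-stream substreams by a fixed integer mixing scheme
  (`derive_seed()`), all below 2³¹; equal config and seed reproduce every
  output bit-identically on one platform, and floating-point comparisons
  in the tests use tolerances of 1e−12 (algebraic identities) down to
  ~1e−2 (detrending-perturbed analytic anchors).
- Phase-trace edge trim: 10 timepoints per end, a documented constant.
- Probability sums are validated to 1e−8; bin-edge equality to 1e−10;
  correlation-matrix symmetry to 1e−8.
- Monte-Carlo suites: effect-recovery margins use 100–200 replicate
  cohorts at 8–12 voxels per network; the family-wise type-I calibration
  uses 500 root seeds × 8-subject groups × 12 voxels per network and
  checks the empirical rate against the binomial 95% interval around
  0.05; the headline cohort is 15 subjects at 24 voxels per network.
  These sizes are the package's chosen trade-off between Monte-Carlo
  resolution and a test suite that runs in minutes.

## Known limitations

- The percent-change statistic is ratio-distributed; its small-sample
  bias is material for slow, heavily autocorrelated traces (the phase
  mode), which is the main reason dispersion is the default estimator.
- Plug-in entropies are biased low at these segment lengths; comparisons
  are therefore always like-with-like (same bins, matched lengths), and
  the optional Miller–Madow flag exists for absolute-value use.
- The brick-wall filter's circular wrap-around is handled by trimming,
  not by padding; for very short records the trim dominates.
- Window length, bin count and threshold defaults are conventions, not
  estimates; all are exposed in the config and swept where conclusions
  could hinge on them.
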