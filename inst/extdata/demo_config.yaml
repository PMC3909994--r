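# Small demonstration run: a 6-subject synthetic cohort at reduced voxel
# count so the full pipeline finishes in seconds. All other parameters are
# the package defaults (12-min scan at TR 3 s, 60-s mid-scan infusion,
# 9 networks, 4 ROIs).
seed: 42
generator:
  voxels_per_network: 12
cohort:
  n_subjects: 6
synchrony:
  mode: phase
entropy:
  n_bins: 10
motifs:
  window_len: 20
  step: 1
  threshold: 0.5
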