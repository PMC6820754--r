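# Demo: synthetic two-group cohort, full directed-connectivity analysis.
# 20-node source space, 8 + 8 subjects, surrogate control enabled so the
# run doubles as a negative-control report.
fs: 600
highpass_hz: 0.5
notch_hz: 50
lowpass_hz: 35
n_epochs: 8
epoch_seconds: 8
exclude_seconds: 60
bins: 16          # occupancy-sized for 4800-sample epochs
n_permutations: 1000
fdr_q: 0.001
seed: 7
surrogate_control: true
simulate:
  n_nodes: 20
  n_edges_common: 8
  n_edges_patient_extra: 6
  strength_patient_extra: 0.6
  n_per_group: 8
  duration: 140
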