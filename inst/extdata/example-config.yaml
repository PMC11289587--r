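# Example circuitburst pipeline configuration.
# Any omitted key keeps its documented default; unknown keys are rejected.
# Note: the ISI-span key must be quoted ("N"), since bare N is a YAML boolean.
network_bursts:
  "N": 20
  merging_fraction: 0.2
  min_channels: 3
  min_contribution_fraction: 0.15
spike_detection:
  band_low: 200
  band_high: 3000
  threshold_multiplier: 4.5
surrogate:
  n_simulations: 5000
  delta_range: [-20, 20]
metrics:
  bin_width: 300
  alpha: 0.05
  family_size: 8
qc:
  rate_limit: 40
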