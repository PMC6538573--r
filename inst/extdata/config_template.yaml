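# pupilprep pipeline configuration template.
# Every key is optional except segmentation.max_missing_pct, which has
# no default: uncomment it and choose a value appropriate for your data.

io:
  time_col: timestamp_s
  left_col: diameter_left_mm
  right_col: diameter_right_mm
  time_units: s          # or "ms"
  # validity_col: validity_left
  # validity_invalid: [0, -1]
  # validity_scope: per_eye

filter:
  range_min_mm: 1.5
  range_max_mm: 9
  speed_mad_multiplier: 16      # tune per dataset
  gap_edge_margin_ms: 50
  gap_min_duration_ms: 75
  deviation_mad_multiplier: 16  # tune per dataset
  deviation_passes: 2
  trendline_cutoff_hz: 4
  sparsity_split_gap_ms: 40
  sparsity_min_section_ms: 50

processing:
  target_rate_hz: 1000
  lowpass_cutoff_hz: 4
  max_interp_gap_ms: 250
  lowpass_order: 1

segmentation:
  # max_missing_pct: 30   # REQUIRED for segmentation; e.g. 30
  bin_ms: 100
  pairing:
    baseline: baseline
    response: trial

plots: true
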