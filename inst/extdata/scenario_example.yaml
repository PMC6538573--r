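# Example synthetic-recording scenario for `pupilprep.R simulate`.
seed: 1
duration_s: 60
rate_hz: 250
timestamp_jitter_pct: 0
base_mm: 4.5
noise_sd_mm: 0.03
eye_offset_mm: 0.3
n_blinks: 3
blink_gap_ms: 120
blink_dip_mm: 0.6
n_spikes: 5
spike_amp_mm: 0.8
n_clusters: 2
cluster_len: 5
cluster_offset_mm: 0.5
n_islands: 1
island_ms: 40
island_flank_gap_ms: 100
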