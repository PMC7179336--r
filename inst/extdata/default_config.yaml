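# Full default analysis configuration (every key shown; all overridable).
bands:
  wideband: [1.6, 30]    # acquisition band: Hjorth, wideband envelope, PSD
  fd: [2, 20]            # fractal-dimension band
  alpha: [8, 13]         # alpha-envelope band
filter:
  order: 12              # effective zero-phase Butterworth order
  mode: zero_phase       # or: causal
artifact:
  threshold_uv: 100      # per-epoch peak amplitude bound
features:
  k_max: 8               # Higuchi maximum lag
  emf_mode: centroid     # or: peak
  emf_cap_hz: 12         # envelope-spectrum centroid cap
  trim_s: 0.5            # envelope edge trim per side
  welch_seg_s: 4         # Welch segment length (s)
stats:
  alpha: 0.05
  r_display: 0.35        # correlation display threshold
  family: channels_within_feature   # or: all_cells
  pooling: channel_mean  # or: per_channel
  rest_condition: rest_closed
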