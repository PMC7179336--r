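# Demo cohort: all five study groups with their default spectral profiles,
# eyes-closed rest plus two emotional sound conditions, an injected
# fast-band effect for the control group under crying (raising the fractal
# dimension during stimulation). Seed is overridden by analysis/01_simulate.R.
seed: 20260101
n_channels: 19
fs: 250
conditions: [rest_closed, crying, barking]
design:
  n_epochs: 2
  epoch_s: 10
groups:
  - name: control
    n_subjects: 6
  - name: schizophrenia
    n_subjects: 6
  - name: mTBI
    n_subjects: 6
  - name: stroke
    n_subjects: 6
  - name: coma
    n_subjects: 6
effects:
  - group: control
    condition: crying
    band: [15, 25]
    gain: 1.5
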