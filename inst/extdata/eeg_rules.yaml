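# Canonical EEG paroxysm rules: prominence over the robust baseline scale,
# period windows in milliseconds.
spike:
  trigger: amplitude
  k: 3
  period_min_ms: 20
  period_max_ms: 70
sharp_wave:
  trigger: amplitude
  k: 3
  period_min_ms: 70
  period_max_ms: 200
spicule:
  trigger: amplitude
  k: 3
  period_min_ms: 70
  period_max_ms: 200
  polarity_change: true
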