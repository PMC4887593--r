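# Broad-band paroxysm rule covering the whole spike/sharp-wave duration
# family; used when classification keys on event features rather than
# sub-type labels.
paroxysm:
  trigger: amplitude
  k: 3
  period_min_ms: 20
  period_max_ms: 400
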