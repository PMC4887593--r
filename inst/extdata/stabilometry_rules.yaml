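# Unilateral-stance fall rule: raised-foot sensor pressure above the
# threshold. Sub-threshold gaps up to 100 ms are bridged and falls shorter
# than 100 ms discarded, so pressure hovering near the threshold does not
# shatter one fall into a burst of sensor chatter.
fall:
  trigger: threshold
  threshold: 50
  min_duration_ms: 100
  merge_gap_ms: 100
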