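# Line-panel attrition under the failure rate calibrated from the
# 450 -> 59 endpoint (15 generations, 3 replicate patches per line).
subcommand: panel
seed: 1
panel:
  n_lines: 450
  generations: 15
  replicates_per_line: 3
  failure_prob: 0.5022232
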