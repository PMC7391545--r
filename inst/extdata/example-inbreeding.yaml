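# Analytic sib-mating inbreeding trajectory from the most-heterozygotic
# founding cross, over the protocol's 15-generation horizon.
subcommand: inbreeding
seed: 1
inbreeding:
  generations: 15
  mode: exact
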