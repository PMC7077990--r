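# Uptake protocol: pyruvate-free baseline, then a cytosolic pyruvate step.
t_end: 420
segments:
  - {name: zero,           t_start: 0,  p_cyt: 0,   inhibition: 0}
  - {name: substrate_step, t_start: 60, p_cyt: 300, inhibition: 0}
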