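# One-point calibration protocol: baseline, forced zero, saturating load.
t_end: 480
segments:
  - {name: baseline,    t_start: 0,   p_cyt: 33,    inhibition: 0}
  - {name: forced_zero, t_start: 120, p_cyt: 0,     inhibition: 0}
  - {name: saturating,  t_start: 300, p_cyt: 10000, inhibition: 0}
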