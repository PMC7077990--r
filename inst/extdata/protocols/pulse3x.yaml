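# Three short partial blocks with recoveries.
t_end: 570
segments:
  - {name: baseline, t_start: 0,   p_cyt: 33, inhibition: 0}
  - {name: block1,   t_start: 120, p_cyt: 33, inhibition: 0.69}
  - {name: recover1, t_start: 150, p_cyt: 33, inhibition: 0}
  - {name: block2,   t_start: 270, p_cyt: 33, inhibition: 0.69}
  - {name: recover2, t_start: 300, p_cyt: 33, inhibition: 0}
  - {name: block3,   t_start: 420, p_cyt: 33, inhibition: 0.69}
  - {name: recover3, t_start: 450, p_cyt: 33, inhibition: 0}
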