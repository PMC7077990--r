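# Transporter-stop flux protocol: forced-zero calibration anchor, baseline,
# then partial carrier block.
t_end: 720
segments:
  - {name: forced_zero, t_start: 0,   p_cyt: 0,  inhibition: 0}
  - {name: baseline,    t_start: 120, p_cyt: 33, inhibition: 0}
  - {name: block,       t_start: 420, p_cyt: 33, inhibition: 0.69}
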