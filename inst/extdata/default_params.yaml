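# Published model parameter set. Units: uM and seconds.
carrier:
  mpc_total: 3.24      # uM, total carrier over all six states
  k_on: 100            # uM^-1 s^-1 (= 1e8 M^-1 s^-1), protons and pyruvate
  k_off_h: 20          # s^-1
  k_off_p: 2120000     # s^-1
  f1: 200              # s^-1, empty-carrier translocation
  f2: 3000             # s^-1, loaded-carrier translocation
boundary:
  p_cyt: 33            # uM, clamped cytosolic pyruvate
  h_cyt: 0.063         # uM  (pH 7.2, rounded)
  h_mit: 0.016         # uM  (pH 7.8, rounded)
sinks:
  v_max_pdh: 1.34      # uM/s
  k_m_pdh: 10          # uM
  v_max_pc: 3.3        # uM/s
  k_m_pc: 220          # uM
sensor:
  k_d: 480             # uM
  df_max: 2.47         # maximal fractional fluorescence change (247%)
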