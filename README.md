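# pyruflux

Kinetic modeling of mitochondrial pyruvate transport and the partitioning of
matrix pyruvate between oxidation and anaplerosis.

## The problem

Pyruvate enters the mitochondrial matrix through the mitochondrial pyruvate
carrier (MPC), a proton symporter of the inner membrane, and is consumed by
two saturable sinks: pyruvate dehydrogenase (PDH, feeding oxidative
metabolism) and pyruvate carboxylase (PC, feeding anaplerosis and
gluconeogenesis). In astrocytes the matrix pyruvate concentration sits in the
low micromolar range — near the PDH Michaelis constant (K_m = 10 µM) and far
below the PC one (K_m = 220 µM). In that regime the carrier is positioned to
control the anaplerotic branch *ultrasensitively*: a fractional change in
carrier activity produces a larger fractional change in PC flux, while the
nearly saturated PDH barely responds.

`pyruflux` is for modelers and cell physiologists who want to analyze this
system quantitatively: simulate the carrier, locate steady states, compute
response coefficients, and run the fluorescence-based estimation protocols
(biosensor calibration, initial-rate fits, transporter-stop flux estimates)
against either real traces or the package's own synthetic single-cell data.

## The model

The carrier is a six-state alternating-access cycle — outward- and
inward-facing conformations, each empty (MPC_o, MPC_i), proton-loaded
(MPC_oH, MPC_iH) or proton+pyruvate-loaded (MPC_oHP, MPC_iHP) — with ordered
binding (H⁺ first, then pyruvate), shared association rate constant
k_on = 10⁸ M⁻¹s⁻¹, dissociation rates k_off,H = 20 s⁻¹ and
k_off,P = 2.12·10⁶ s⁻¹, and translocation rates f₁ = 200 s⁻¹ (empty) and
f₂ = 3000 s⁻¹ (loaded); proton-only forms do not translocate. Matrix
pyruvate obeys

    dP_i/dt = k_off,P·[MPC_iHP] − k_on·[MPC_iH]·P_i − v_PDH(P_i) − v_PC(P_i)

with Michaelis–Menten sinks v(P) = V_max·P/(K_m + P), total carrier
3.24 µM, cytosolic pyruvate clamped (33 µM at baseline) and protons fixed at
pH 7.2 / 7.8 (63 / 16 nM). All internal units are µM and seconds.

On top of the mechanistic core the package implements the measurement
machinery: the hyperbolic single-fluorophore sensor model
(ΔF/F₀ = ΔF_max·P/(K_D + P), K_D = 480 µM, ΔF_max = 247%), one-point
in-cell calibration against a forced-zero segment, isosbestic-ratio pH
correction, single-exponential initial-rate fitting, and transporter-stop
depletion-rate estimation.

## Worked example

```r
library(pyruflux)

ss <- solve_system_steady_state()
ss
#> Steady state: matrix pyruvate 21.13 uM
#> Fluxes (uM/s): transport 1.199, PDH 0.9096 (75.9%), PC 0.2892 (24.1%)

fit_zero_trans_km()
#> Zero-trans kinetics: K_zt 139.6 uM, apparent Vmax 8.396 uM/s (RMS resid 1e-14 of Vmax)

response_coefficient("pc_flux", "mpc_total")
#> Response of pc_flux to mpc_total: 1.189 %/% (delta = 0.01)
response_coefficient("pdh_flux", "mpc_total")
#> Response of pdh_flux to mpc_total: 0.4155 %/% (delta = 0.01)

ultrasensitivity_scan()
#> Ultrasensitivity scan (mpc_total axis, 48 points): amplification threshold 30.1 uM matrix pyruvate
```

Read: with the reference parameters the coupled system settles at 21 µM
matrix pyruvate, with transport (1.2 µM/s) split 76%/24% between PDH
(0.91 µM/s) and PC (0.29 µM/s). A 1% increase in carrier dosage raises PC
flux by ~1.2% but PDH flux by only ~0.4%, and that amplification (response
coefficient > 1) persists for all operating points with matrix pyruvate
below ~30 µM.

A synthetic transporter-stop experiment, end to end:

```r
cell <- generate_cell(seed = 42)                      # 2% noise by default
cal  <- one_point_calibrate(cell$f488, zero_window = c(10, 110))
stop_depletion_rate(cal$concentration, t_block = 420, method = "saturable")
#> Transporter-stop estimate (saturable): depletion 0.7726 uM/s; plateau 17.3% of pre-block level
cell$truth$consumption_at_block * cell$truth$inhibition
#> [1] 0.8271231
```

The estimate divided by the known inhibited fraction (0.69) recovers the
cell's total consumption; across seeded populations the recovery is
unbiased (see the methods vignette for the noise floor discussion).

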