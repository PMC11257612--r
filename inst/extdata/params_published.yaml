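# Population-median parameter values per background concentration.
# Gains (G_r * k_D, units 1/k_D) were measured separately at each background;
# sigma_v2, tau_v, tau_2, D_n and tau_n depend only weakly on background, and
# the values measured at c0 = 1 uM stand in for the other backgrounds here
# (synthetic stand-in for the per-background tables that are not reproduced).
capture:
  D_ligand: 800        # um^2/s
  l_sensor: 0.06       # um
mwc:
  G_inf: 3.5
  K_i: 0.81            # uM
kinase:
  tau_1: 0.0           # s (CheY/CheZ relaxation folded out; see docs)
  a0: 0.33             # steady-state activity (typical FRET-derived level)
swim_kinematics:
  # bout statistics: field-typical values; speed and d_rot are calibration
  # outputs of calibrate_swim_phenotype() targeting sigma_v2, tau_v at 1 uM
  mean_run: 1.0        # s
  mean_tumble: 0.15    # s
  persistence: 0.33
  speed: 18.38         # um/s  (calibrated)
  d_rot: 0.2151        # rad^2/s (calibrated)
backgrounds:
  - c0: 0.1
    G_r_kD: 3.2
    G_r_kD_sigma: 0.1
    sigma_v2: 146.0
    tau_v: 1.19
    tau_2: 7.4
    D_n: 8.1e-4
    tau_n: 8.7
  - c0: 1.0
    G_r_kD: 2.28
    G_r_kD_sigma: 0.05
    sigma_v2: 146.0
    tau_v: 1.19
    tau_2: 7.4
    D_n: 8.1e-4
    tau_n: 8.7
  - c0: 10.0
    G_r_kD: 0.251
    G_r_kD_sigma: 0.009
    sigma_v2: 146.0
    tau_v: 1.19
    tau_2: 7.4
    D_n: 8.1e-4
    tau_n: 8.7
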