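# Shared fixtures: population-median phenotypes measured at c0 = 1 uM, and a
# calibrated run-tumble phenotype (computed once per test run).

published <- load_params()
kD_ref <- capture_rate_constant(800, 0.06)

env_1uM <- function(g = 0) environment_spec(c0 = 1, g = g)

swim_median <- swimming_phenotype(sigma_v2 = 146, tau_v = 1.19)

kin_median <- function(tau_1 = 0, G_r_kD = 2.28) {
  kinase_phenotype(G_r = G_r_kD / kD_ref, tau_1 = tau_1, tau_2 = 7.4,
                   D_n = 8.1e-4, tau_n = 8.7, a0 = 0.33)
}

# calibrated kinematics: reuse the shipped calibration outputs (themselves
# produced by calibrate_swim_phenotype(); the calibration routine is tested
# separately)
swim_calibrated <- local({
  sk <- published$swim_kinematics
  swimming_phenotype(sigma_v2 = 146, tau_v = 1.19, speed = sk$speed,
                     p_run = sk$mean_run / (sk$mean_run + sk$mean_tumble),
                     mean_run = sk$mean_run, mean_tumble = sk$mean_tumble,
                     persistence = sk$persistence, d_rot = sk$d_rot)
})
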