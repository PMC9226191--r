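# Nominal (healthy) model parameters.
# Flat key/value map; keys are exactly the ModelParameters field names.
# Units: G, Km_*, PYR_E_star, PEP_star in mM; Vmax_* in mM/min;
# psi_* in 1/min; lambda_* in 1/mM; the rest dimensionless.
G: 5                    # external choroidal glucose
GLUT1: 1                # relative transporter level, healthy = 1
c_M1: 1                 # MCT1 regulatory constant, healthy = 1
lambda_E: 0.8
lambda_r: 21.7e-3
lambda_LACT_Ex: 480
Vmax_g_E: 1.2
Km_g_E: 9
Vmax_G6P_E: 0.00738
Km_G6P_E: 0.002844
Vmax_F16BP_E: 1.2285
Km_F16BP_E: 0.1106
Vmax_PYR_E: 0.00783
Km_PYR_E: 0.17
Vmax_PYR_rE: 14
Km_PYR_rE: 0.125
Vmax_g_r: 0.8
Km_g_r: 8
Vmax_G6P_r: 0.1845
Km_G6P_r: 0.09
Vmax_NADPH_r: 0.228
Km_NADPH_r: 0.45
Vmax_F16BP_r: 1.365
Km_F16BP_r: 3.5
Vmax_PYR_r: 0.3915
Km_PYR_r: 0.06
Vmax_G3P_r: 0.15
Km_G3P_r: 0.143
Vmax_LACT_r: 0.14
Km_LACT_r: 1.25e-5
psi_PYR_E: 710
psi_NADPH_r: 15e2
psi_LACT_r: 96e2
psi_G3P_r: 0.02
PYR_E_star: 4.6e-5
PEP_star: 1.65e-13
q_r: 0.18
rho_r: 1e-3
R_p: 1.0                # G3P clearance multiplier; no tabulated value, inert in normalized results
delta_r: 13e8           # carried for fidelity; referenced by no rate law
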