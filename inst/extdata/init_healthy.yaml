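# Nominal initial metabolite concentrations (mM), state order fixed.
g_E: 3
G6P_E: 5e-3
F16BP_E: 0.13
PYR_E: 0
g_r: 0.1
G6P_r: 0.45
NADPH_r: 0.1e-8
F16BP_r: 0.06
G3P_r: 2.5e-6
PYR_r: 0
LACT_r: 1e-4
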