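beam,energy_mev_u,let_kev_um,mu_grain_4um,sd_grain_4um,mu_grain_38um,sd_grain_38um,mu_single_crystal,sd_single_crystal
H230,226.5,0.41,1.02,0.03,0.97,0.03,0.77,0.06
H160,154.5,0.54,1.01,0.02,0.96,0.03,0.76,0.07
He150,142.6,2.25,0.95,0.02,0.90,0.02,0.71,0.07
C400,383.2,11.22,0.75,0.04,0.71,0.03,0.56,0.08
C290,273.8,13.50,0.73,0.03,0.69,0.02,0.55,0.08
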