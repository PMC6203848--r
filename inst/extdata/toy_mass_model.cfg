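alpha_mass: 47
omega_mass: 75
delta_left: 1.3
delta_right: 0.9
adduct_mass: 22.989218
charge: 1
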