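k_D: 300.0
k_plus: 30.0
k_minus: 40.0
E_NL: 1.4
d_plus: 2.0
d_minus: 2.0
v_II0: 30.0
k_bT: 1.0
k_bD: 0.0
d: 8.0
kBT: 4.1
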