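3
synthetic h_oh_ts fixture geometry (Angstrom)
H      0.000000     0.000000     0.000000
H      1.000000     0.000000     0.000000
O      2.200000     0.000000     0.000000
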