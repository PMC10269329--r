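3
synthetic hnc_ts fixture geometry (Angstrom)
N      0.000000     0.000000     0.000000
C      1.190000     0.000000     0.000000
H      0.550000     1.250000     0.000000
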