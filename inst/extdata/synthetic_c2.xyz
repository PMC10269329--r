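2
synthetic c2 fixture geometry (Angstrom)
C      0.000000     0.000000     0.000000
C      0.000000     0.000000     1.242500
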