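5
synthetic c5h5 fixture geometry (Angstrom)
C      0.000000     1.207924     0.000000
C     -1.148804     0.373269     0.000000
C     -0.710000    -0.977231     0.000000
C      0.710000    -0.977231     0.000000
C      1.148804     0.373269     0.000000
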