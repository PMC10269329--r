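{
  "n_electrons": 4,
  "spin": 2,
  "orbitals": [
    {"index": 1, "atom": "H1", "symmetry": "sigma"},
    {"index": 2, "atom": "H2", "symmetry": "sigma"},
    {"index": 3, "atom": "O1", "symmetry": "sigma"},
    {"index": 4, "atom": "O1", "symmetry": "pi"}
  ],
  "criteria": {"priority": ["intra_atomic", "bond_length"]}
}
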