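# vbstruct — chemically insightful valence bond structure sets

Classical valence bond (VB) theory writes a wavefunction as a linear
combination of HLSP structures: spin functions that singlet-couple electron
pairs in localized active orbitals, leave `2S` electrons unpaired, and fix a
lone-pair/vacancy placement.  The full structure list is overcomplete, so a
complete *linearly independent* subset must be chosen — and which subset you
choose determines how interpretable the wavefunction is.  The textbook
recipe (Rumer's non-crossing circle rule) is easy but restrictive: it
depends on the orbital numbering, and in many systems it cannot include the
structures a chemist actually wants (the Kekulé set of an odd cyclic
radical, or intra-atomic-bond-free sets).

`vbstruct` is for VB/VBSCF practitioners preparing structure sets for
programs such as XMVB, and for anyone studying the combinatorics of spin
couplings.  It provides:

* **Enumeration** — every HLSP structure of an `n`-orbital/`Ne`-electron/
  spin-`S` active space, grouped into lone-pair/vacant subspaces, with the
  closed-form count `sum_d C(n,d) C(n-d,v) N!/(2^p p! (2S)!)`.
* **A full Rumer engine** — non-crossing filter with dummy centers for
  radicals, per-ordering set generation, distinct-set enumeration over all
  `N!` orderings with deduplication, and the `N!/(2r)` closed form as a
  cross-check.
* **Chemical-insight ranking** — five criteria (user-defined bonds, user
  radicals, intra-atomic bonds, bond length vs covalent radii, orbital
  symmetry), merged lexicographically via `S_new = (S_n - 1) max(S_m) + S_m`;
  rank 1 is best.
* **Greedy independent-set selection** — candidates in ranked order, each
  accepted iff the Gramian of unit-normalized determinant vectors keeps all
  `|eigenvalue| > 1e-11`; supports pinning must-have structures.  The
  branching-diagram count `N_IS = C(N, N/2-S) - C(N, N/2-S-1)` fixes the
  set size.
* **Chirgwin–Coulson weights** `W_i = c_i Σ_j c_j S_ij / (c'Sc)` for
  externally computed coefficients/overlaps, plus XYZ, JSON-config and
  plain-text matrix readers and a small CLI.

## Worked example: the cyclopentadienyl radical

Five π electrons in five π orbitals, doublet.  A complete set has
`count_independent(5, 1/2) = 5` structures.  Rumer rules can never produce
the five Kekulé structures (any sequential Rumer set spreads over **6**
distinct bonds; the Kekulé set needs only the **5** adjacent ones).  The
insight selector, ranking by intra-atomic bonds then bond length on the
pentagon geometry, finds them directly:

```r
library(vbstruct)
sys <- builtin_system("c5h5")
set <- select_insightful_set(sys$space, config = sys$config,
                             geometry = sys$geometry)
print(set)
#> Structure set (5 structures, subspace D{}V{})
#>    1. 5 1-2 3-4                      [selected]
#>    2. 3 1-2 4-5                      [selected]
#>    3. 4 1-5 2-3                      [selected]
#>    4. 2 1-5 3-4                      [selected]
#>    5. 1 2-3 4-5                      [selected]
#> Gramian 5x5: min |eigenvalue| = 2.865e-01 (threshold 1.0e-11) -> independent
```

Each line is one structure in occupancy notation — e.g. `5 1-2 3-4` is the
radical on orbital 5 with singlet bonds 1–2 and 3–4 — all five are Kekulé
(adjacent-bond) structures, and the Gramian certifies independence.

```r
count_distinct_bonds(generate_rumer_set(sys$space))  # 6  (any Rumer set)
count_distinct_bonds(set)                            # 5  (Kekulé set)
chirgwin_coulson_weights(c(0.6, 0.8), diag(2))       # 0.36 0.64
```

Other built-ins: `"c2"` (8e/8o singlet; 14 structures per set, 2520
distinct Rumer sets, 336 containing the quadruple-bond pairing),
`"hnc_ts"` (6e/5o; 5 lone-pair subspaces × 2), `"h_oh_ts"` (4e/4o triplet
with the pinnable reaction structures).

A CLI wrapper lives at `inst/cli/vbstruct`:

```sh
Rscript inst/cli/vbstruct select --system c5h5
Rscript inst/cli/vbstruct count --config inst/extdata/h_oh_ts_config.json
```

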