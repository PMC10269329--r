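Package: vbstruct
Title: Chemically Insightful Valence Bond Structure Sets
Version: 0.1.0
Authors@R: person("vbstruct", "developers", role = c("aut", "cre"),
    email = "vbstruct@example.org")
Description: Generation, ranking and selection of complete linearly
    independent sets of Heitler-London-Slater-Pauling (HLSP) valence bond
    structures.  Enumerates every spin-paired structure of an active space,
    implements the classical Rumer non-crossing rules (including dummy
    centers for unpaired electrons) and their set combinatorics, scores
    structures by chemical-insight criteria (user-defined bonds and
    radicals, intra-atomic bonds, bond lengths against covalent radii,
    orbital symmetry) merged lexicographically, and greedily assembles
    highest-quality independent sets certified by a Gramian eigenvalue
    test.  Chirgwin-Coulson weights are provided as a utility for
    externally computed coefficients and overlaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
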