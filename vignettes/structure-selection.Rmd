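---
title: "Selecting chemically insightful valence bond structure sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting chemically insightful valence bond structure sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A classical valence bond (VB) wavefunction is a linear combination of
Heitler-London-Slater-Pauling (HLSP) spin functions: each "structure"
singlet-couples pairs of electrons in localized active orbitals, leaves $2S$
electrons unpaired, and fixes a placement of lone pairs and vacancies.  The
set of all such structures is overcomplete.  Any complete linearly
independent subset spans the same space, so the *choice* of subset is purely
a matter of interpretability -- and the classical recipe, Rumer's
non-crossing rule, is restrictive: it depends on an arbitrary orbital
numbering, forbids certain chemically central structures outright (in odd
cyclic systems the bond between the first and last orbital can never
appear), and often forces structures with intra-atomic singlet pairs.

`vbstruct` implements both sides of this trade:

* a full Rumer engine (circle orderings, dummy centers for radicals,
  non-crossing filter, and the combinatorics of distinct Rumer sets over all
  orbital orderings), used as a baseline and a test target, and
* a criteria-driven *chemical insight* selector that ranks every structure
  of a subspace and greedily assembles the best linearly independent set.

## Counting and enumeration

For $n$ active orbitals, $N_e$ electrons, and spin $S$, a structure with $d$
lone pairs has $N = N_e - 2d$ singly occupied orbitals, $p = N/2 - S$ bonds,
and $2S$ radicals.  The number of structures per occupancy placement is
$N! / (2^p \, p! \, (2S)!)$, and placements contribute
$\binom{n}{d}\binom{n-d}{v}$ with $v = n - d - N$ vacancies.  The closed
form is verified in the test suite against exhaustive enumeration (the
enumeration, not the formula, is treated as ground truth, because the
formula was reconstructed from a displayed-image equation in the source
literature).  We additionally allow *mixed* occupancies ($d$ lone pairs
**and** $v$ vacancies in one structure), which arise for charged or
non-stoichiometric active spaces; the all-covalent and all-vacant cases of
the literature are the special cases $v = 0$ and $d = 0$.

Enumeration order is canonical -- sorted by subspace key, then bond list,
then radical list -- so all downstream tie-breaking is deterministic across
platforms.

## Independence: determinant vectors and the Gramian

Each structure is expanded over spin-orbital determinants at the highest
spin projection $M_S = S$: every pair $(a,b)$ contributes
$(\alpha_a\beta_b - \beta_a\alpha_b)$, radicals are $\alpha$, and lone pairs
contribute a fixed $\alpha\beta$ factor that is dropped from the expansion
keys.  Working at a single $M_S$ is sufficient: spin eigenfunctions of equal
$S$ are linearly independent if and only if any fixed-$M_S$ component set
is.

A candidate set is independent when its Gram matrix of structure-vector
inner products has no eigenvalue with absolute value at or below the
threshold, default $10^{-11}$, matching standard VB practice.  Two
numerical choices are deliberate:

* **Normalization.**  Structure vectors are unit-normalized before the
  Gramian is formed, making the absolute eigenvalue threshold scale-free
  (otherwise a structure with many pairs would inflate or deflate
  eigenvalues by powers of $\sqrt 2$).  The source literature does not state
  a normalization; this is our choice and is flagged here.
* **Sign convention.**  Determinant keys list orbitals in ascending global
  order and pair factors multiply in ascending order of their smaller
  index.  Any consistent alternative flips at most the overall sign of a
  vector; tests assert that overlap magnitudes and eigenvalue spectra are
  invariant under reordering.

The branching-diagram count
$N_{IS} = \binom{N}{N/2-S} - \binom{N}{N/2-S-1}$ gives the target set size
per subspace, and the suite cross-checks it against the exact rank (QR) of
the full enumerated vector matrix for $N \le 8$.

## The Rumer engine

Singly occupied orbitals are placed on a circle in a chosen order; one dummy
center per radical is appended after the last real orbital, dummy-dummy
bonds are forbidden, and a structure is allowed when no two chords cross.
With several dummies we accept a structure if *some* assignment of radicals
to dummy centers is non-crossing; assignments differ only by permuting
interchangeable placeholders, so this matches the pictorial rule without
imposing an arbitrary radical order.

Distinct Rumer sets are enumerated by running the construction over all
$N!$ orderings and deduplicating by set identity.  The implementation
precomputes the non-crossing *position* templates once (for even $N$, $S=0$
there are Catalan$(N/2)$ of them) and remaps them through each permutation,
which keeps the 8-orbital case (40320 orderings, 14 templates) at around
half a minute.  The closed form $N!/(2r)$ -- $r$ the rotation order of the
cycle for even $N$, $r = 1$ for odd $N$ -- is used only as a test oracle.
Its $N = 2$ evaluation ($2!/4 = 1/2$) shows the formula's domain edge:
reflection and rotation coincide there, so the implementation clamps the
count below at 1, and brute-force deduplication confirms the single set.

## Ranking criteria

Five integer scores, rank 1 best, one penalty point per offence:

| criterion | score | needs |
|---|---|---|
| user-defined bonds | $N_B - N_{UDB} + 1$ | nonempty UDB set |
| user-defined radicals | $N_R - N_{UDR} + 1$ | nonempty UDR set |
| intra-atomic bonds | $N_{IAB} + 1$ | orbital-to-atom map |
| bond length | dense rank of $D_{NAB}$ | geometry (XYZ, Angstrom) |
| orbital symmetry | $N_{SBB} + 1$ | symmetry labels |

The affine forms above were reconstructed from the textual definitions of
the variables (the printed equations are images in the source); they are the
unique linear forms consistent with "rank 1 is best" and one-point
increments, and the tests pin this behaviour.

For the bond-length criterion the stretch measure is
$D_{NAB} = \sum_k \max(0,\, R_k - R_k^{cov}) / R_k^{cov}$ over inter-atomic
bonds $k$, where $R^{cov}$ is the sum of tabulated crystallographic covalent
radii (Cordero et al. 2008 values, user-overridable).  Bonds no longer than
$R^{cov}$ -- "neighbouring atom bonds" -- contribute zero, and intra-atomic
bonds contribute zero by construction.  Whether the source used differences
or ratios of $R$ and $R^{cov}$ is not recoverable from the text; only the
*induced ranking* is consumed downstream, and any monotone variant induces
the same ranking, so the choice is inconsequential for set selection.  Ties
receive dense ranks (1, 1, 2, ...), avoiding order-dependence that a
"sequential number" rank would introduce.  Because this criterion changes
with geometry, `criteria_config()` warns when it is the top or only
priority.

Unlabelled orbitals share one wildcard symmetry label: two unlabelled
orbitals count as same-symmetry, an unlabelled-labelled bond counts as
symmetry-breaking.  Formal charges are never compared -- structures with
different lone-pair/vacancy placements belong to different subspaces and are
ranked separately.

Scores merge pairwise in priority order via
$S_{new} = (S_n - 1)\max(S_m) + S_m$, which realizes exactly the
lexicographic order of the per-criterion tuples (property-tested against a
brute-force tuple sort).

## Greedy selection

Per subspace, candidates are sorted by unified score (ties broken by the
canonical enumeration order), pinned structures go first after a mutual
independence check, and each next candidate is accepted iff the grown
Gramian stays above threshold, until $N_{IS}$ structures are reached.  Two
small deviations from a literal reading of the source procedure:

* the initial pair is *checked*, not assumed independent (degenerate
  subspaces can make the first two sorted candidates dependent);
* after pinning, the globally sorted candidate order is kept rather than
  re-sorted, so pinning never changes relative candidate priorities.

The Gramian is recomputed from scratch per candidate; sets are at most a
few dozen structures, so incremental updates would buy nothing but
complexity.  Selection is greedy by construction -- no global optimization
over all complete sets is attempted -- but a swap-optimality property (no
outside candidate with a strictly better score could replace a member while
preserving independence) is verified by brute force on the 15-candidate
pentagon space.

## Fixtures and what a green test establishes

Four built-in systems mirror the standard demonstration cases: the
cyclopentadienyl radical (5e/5o doublet), the C2 molecule (8e/8o singlet),
and the H+OH and HNC hydrogen-transfer transition states (4e/4o triplet,
6e/5o singlet).  Their *combinatorics* (set sizes 5/3/10/14, the 2520
distinct 8-orbital Rumer sets, the 336 containing the quadruple-bond
pairing, 6 vs 5 distinct bonds for pentagon Rumer vs Kekulé sets) are exact
and fully reproduced.

The geometries, however, are synthetic stand-ins: a regular pentagon with
1.42 Å sides, a 1.24 Å C-C diatomic, near-linear transition-state
arrangements with partially stretched bonds.  They are topologically
faithful -- the bond-length criterion consumes only relative distance
orderings, which these geometries reproduce -- but they are *not* the
published quantum-chemistry geometries, so no test here validates absolute
distances or energies.  Likewise, VBSCF structure *weights* require an
electronic-structure engine and are out of scope; the Chirgwin-Coulson
weight utility ($W_i = c_i \sum_j c_j S_{ij} / c^T S c$) is validated by its
conservation law ($\sum_i W_i = 1$) and closed-form cases, and accepts
externally computed coefficients and overlaps.

## Limitations

* No orbital optimization, integrals, or non-orthogonal orbital overlaps:
  structure overlaps here are spin-coupling overlaps at orthogonal orbitals,
  exactly what the independence decision needs and nothing more.
* Distinct-Rumer-set enumeration is guarded at $N \le 10$; beyond that,
  sample orderings instead.
* The ionic-structure support is occupancy bookkeeping only; no charge
  semantics are attached.
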