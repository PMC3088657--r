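---
title: "Ligand transference across protein-chemical complex structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand transference across protein-chemical complex structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligtrans)
```

## The idea

The database of solved structures is a bipartite network: protein chains on
one side, small molecules on the other, and an edge wherever a structure
shows the two in contact. When two proteins P1 and P2 share a bound ligand
La, and P1 has additionally been solved with a second ligand Lb, the two
binding events can be composed geometrically: superimpose P1's two
structures onto each other (carrying Lb along), then superimpose the two La
copies (carrying everything into P2's frame). The result is a putative
complex P2:Lb that no one has solved. Whether that putative complex is
*structurally sensible* — ligand in a pocket, no steric disaster, polar
atoms paired — is a question the package answers with an empirical score
calibrated against deliberately nonsensical complexes.

The method predicts whether a crystal-structure-like arrangement is
*possible*; it says nothing about affinity. Conformational change is not
modelled: a transfer only succeeds when the ligand conformation from the
donor structure fits the acceptor pocket as-is, and the scoring stage is
what rejects the rest.

## The two-stage superposition

`build_prediction()` composes two rigid maps, in this order:

1. **Protein stage.** The P1:Lb structure is mapped onto the P1:La
   structure by Kabsch superposition over corresponded C-alpha atoms. The
   correspondence comes from a global Needleman-Wunsch alignment (BLOSUM62,
   gap open 11, extend 1); for remote pairs a two-column residue
   correspondence file can replace the alignment
   (`read_correspondence()`). If the alignment covers fewer than
   `min_ca_pairs` (default 30) C-alpha pairs the candidate is rejected
   rather than built from a flimsy fit.
2. **Ligand stage.** The P1:La structure is mapped onto the P2:La structure
   by Kabsch superposition over the common ligand's heavy atoms. Atom
   pairing uses matching atom names when available, otherwise VF2
   isomorphism of the element-labelled bond graphs; among symmetry-
   equivalent mappings the one minimising the fitted RMSD wins.

Lb's coordinates traverse both maps; P2 never moves. The order matters —
re-centering on the common ligand is what drops Lb into P2's pocket — and a
regression test keeps the composition from being silently swapped.
Superposition is rigid throughout: the transferred ligand's internal
distance matrix is preserved to numerical precision, which the test suite
asserts at 1e-6 Angstrom.

Sequence identity is reported with the shorter sequence as denominator, the
conservative common convention; the alignment parameters are fixed and
recorded rather than tunable, because the identity values feed hard filters
(below) and silent parameter drift would move those filters.

## The seven descriptors and the empirical score

For a (putative) complex the package computes, over heavy atoms only:

| descriptor | meaning | direction |
|---|---|---|
| a | clash volume (A^3): overlap of ligand and protein vdW spheres | detrimental |
| b | protein-ligand contacts within 5.0 A | beneficial |
| c | donor/acceptor pairs at 2.5-3.5 A with compatible typing | beneficial |
| d | pairs inside the vdW window (r_i + r_j - 0.6, r_i + r_j + 0.5] | beneficial |
| e | ligand donor/acceptor atoms with no partner under rule c | detrimental |
| f | ligand carbons with no partner under rule d | detrimental |
| g | ligand donor/acceptor atoms with > 5 A^2 accessible area | detrimental |

Each raw value is normalised against a reference distribution from decoy
complexes: for beneficial descriptors, the fraction of decoy values
*strictly below* the query; for detrimental ones, the fraction *strictly
above*. Ties therefore contribute nothing — a query value sitting exactly on
a decoy mass point scores 0 for that component, the conservative reading of
a strict inequality, and the one property the normalisation tests pin down.
The seven components sum to a combined score S in [0, 7]; improving any
descriptor in its beneficial direction can never lower S (tested by
perturbation over a fixture grid).

The p-value is the strict exceedance fraction among the decoys' own
combined scores: `p = #(sigma > S) / #sigma`. No continuity correction; a
score above every decoy is stored as p = 0 and printed as "< 1/n".

### The decoy null

`generate_negatives()` builds the reference: pick two complexes at random,
translate each ligand so its heavy-atom centroid lands on the other
ligand's centroid — no rotation, no optimisation — and keep the result only
if it neither clashes severely (some atom pair closer than half the sum of
vdW radii) nor loses all contact (fewer than two pairs within 5 A). These
are random fits of real ligands into real pockets: plausible enough to
populate every descriptor's distribution, wrong enough to define a null.

The decoys' own scores (the sigma array) are computed leave-one-out: each
decoy is ranked against the remaining n-1, exactly as a query is ranked
against all n. Under that construction the decoys' p-values are uniform on
[0, 1] up to discreteness, and the calibration test demands a
Kolmogorov-Smirnov statistic below the 1% critical value at n = 2,000.
A robustness property from the method's validation is mirrored at desk
scale: restricting the reference to decoys whose ligand has the query's
heavy-atom count leaves score rankings essentially unchanged (rank
correlation at least 0.9 on a fixture panel).

### Numerical choices

The geometric thresholds above are package decisions, recorded in
`scoring_config()` and stamped into every reference's metadata: hydrogen
bond window 2.5-3.5 A, vdW window -0.6/+0.5 A around the radius sum, Bondi
radii, SASA by Shrake-Rupley with a 1.4 A probe and 192 golden-spiral
points per atom, exposure threshold 5 A^2, clash volume on a 0.25 A grid
over the ligand's padded bounding box. Grid points inside both sphere
unions are counted once, so multi-atom overlap is never double-counted; the
suite checks the grid against closed-form sphere-lens volumes (within 5%)
and against a halved spacing (within 2%). Near-tangent sphere pairs are the
known weak spot of any fixed grid — at centre distance 3.0 A for two
carbons the lens is thinner than the grid step and the relative error grows
— which is immaterial here because clash volume only needs to *rank*
overlaps, not resolve grazing contacts.

The decoy-rejection clash rule (half the vdW sum) is deliberately much
harsher than the graded clash-volume descriptor: rejection should only
remove physically absurd decoys, because removing every clashing decoy
would degenerate descriptor a's null distribution to a point mass at zero.

## The candidate network and its filters

`build_network()` keys protein nodes by exact sequence and chemical nodes
by the canonical form (BLISS) of the element-labelled heavy-atom bond
graph; every complex is an edge, and a pair solved repeatedly carries
multiple edges. `enumerate_triplets()` then emits every (P1, P2, La, Lb)
combination and filters:

* **identity < 80%** between P1 and P2 — transfers between near-identical
  proteins are trivial orthology;
* **La and Lb not chemically identical** — implemented as graph identity.
  The fingerprint Tanimoto (hashed circular substructure fingerprint,
  radius 2, 2048 bits, implemented in the package) is computed and
  reported, but is not itself the filter: substructure fingerprints
  saturate at 1.0 for homologous molecules of different size (a C10 and a
  C20 alkane share every radius-2 atom environment), and such pairs are
  legitimate transfers;
* **heavy-atom counts within two-fold** of each other.

Predictions that survive construction are additionally screened by the same
severe-clash rule used for decoys before scoring. Labels from
`classify_prediction()` mark how surprising a prediction is: `easy_protein`
(identity >= 30%, reachable by homology modelling), `easy_chemical`
(Tanimoto >= 0.90, reachable by similarity searching), `solvent_involved`,
or `nontrivial`. The 30% rule stands in for the original family-membership
criterion; no external family database is consulted.

Point mutants of one protein remain distinct nodes (exact-sequence keying)
and are instead removed by the 80% filter at enumeration — one threshold
fewer to tune.

## What the synthetic fixtures are, and are not

`make_pocket_complex()` builds a rigid shell of C-alpha pseudo-residues at
a controlled clearance ("tightness", default 3.5 A) outside a template
ligand's support, with a seeded random sequence; `ligand_template()` ships
eight small molecules with explicit bond graphs (alkane, benzene, triol,
adenine-like fused heterocycle, carboxylate, 20-atom macrocycle, plus an
ethanol/ether isomer pair for graph tests). `make_ground_truth_triplet()`
rigidly scatters one master complex into the three triplet roles, so the
correct answer is known to machine precision.

These fixtures exercise every geometric and statistical code path with
known ground truth, and they are deliberately not folded proteins: no
secondary structure, no side chains, no correlation between sequence and
geometry. Tests passing on them demonstrate the correctness of the
machinery — superposition, descriptor arithmetic, calibration, filtering —
not the biological accuracy of any particular prediction. Accession-based
checks on real structures (`dhfr_trimethoprim_example()`,
`grp94_radicicol_example()`) complement them whenever the referenced PDB
entries are available as local files.

Problem sizes used by the default test run and the acceptance script were
chosen as the smallest that make the statistics meaningful: a 2,000-decoy
reference for calibration (the KS critical value at 1% is then 0.036,
comfortably above the discreteness floor of ~1/n), 40-complex pools for
decoy generation, shells of 50-250 pseudo-residues. The method itself is
size-agnostic; a production reference would use the 100,000-decoy scale
with identical code.

## Degenerate inputs and tie-breaking

* Alternate locations: highest occupancy wins, ties to file order; first
  model of multi-model files.
* Non-solvent HET groups need >= 4 heavy atoms (monoatomic ions are not
  ligands here); solvents are kept but flagged, from a configurable
  plain-text list.
* Bond graphs: component dictionary order is SDF if supplied, else
  distance-based perception (covalent radii + 0.45 A).
* Kabsch on fewer than 3 points is an error; collinear point sets warn
  (the rotation about the axis is unresolved) but return the least-squares
  solution; reflections are never returned.
* Ligand superposition needs >= 3 mapped heavy atoms, so waters and ions
  can never anchor a transfer.
* `p = 0` is stored as zero (the formula's value) and printed as "< 1/n".

## Known limitations

* Protein superposition is sequence-alignment-guided; truly
  non-homologous shared-ligand pairs need a user-supplied correspondence
  file. Full sequence-independent structure alignment is out of scope.
* Donor/acceptor typing is heuristic (element plus bond degree);
  protonation states, tautomers and charged termini are not modelled, and
  protein-side unsatisfied polar atoms are deliberately not counted in
  descriptor e.
* Only the ligand side of the interface is scored; crystal-packing
  artefacts in the input structures are invisible to the method.
* Covalent ligands and nucleic-acid chains are not handled.
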