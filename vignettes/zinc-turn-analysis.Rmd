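---
title: "Mining and modelling the zinc-binding CXXHX alpha-turn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and modelling the zinc-binding CXXHX alpha-turn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincturn)
```

## The scientific problem

Structural zinc sites built from two cysteines and two histidines are
among the most common metal centers in proteins. A recurring local
arrangement places the Cys and His only three residues apart, in a
five-residue **C-X1-X2-H-X3** segment folded as an α-turn: the Cα atoms
of residues *i* and *i+4* approach to ≤ 7 Å, typically closed by an
*i* → *i+4* hydrogen bond. When both the Cys thiolate and a His ring
nitrogen coordinate the same Zn²⁺, the segment becomes a compact,
portable chelating unit — the kind of unit a protein designer can graft
into a minimal peptide and dimerize around a tetrahedral metal.

`zincturn` implements the full retrostructural workflow around this
motif: mining it from coordinate files, characterizing its conformation,
clustering the population, reconstructing C2-symmetric dimer models, and
— on the experimental side — solving and fitting the self-assembly
binding equilibria of the corresponding designed metallopeptides.

## Mining model and its assumptions

A zinc site is an inventory of heavy atoms within a coordination cutoff
of a Zn ion. The cutoff defaults to **3.0 Å**: the survey literature
reports mean bond lengths of 2.34 ± 0.07 Å (Sγ–Zn) and 2.1 ± 0.1 Å
(N–Zn), so 3.0 Å covers both with margin while excluding second-shell
atoms; it is configurable (`find_zinc_sites(cutoff=)`). A motif is
emitted only when the position-1 Cys Sγ and a position-4 His ring
nitrogen are ligands of the *same* zinc, the five residues are
consecutive in author numbering with no insertion codes inside the
window, and both terminal Cα atoms are present. The His donor is the
ring nitrogen nearer the metal; when Nδ1 and Nε2 are within 0.1 Å of
each other the motif is flagged ambiguous rather than silently assigned.

The α-turn filter is boundary-inclusive (`ca_distance ≤ 7.0 Å`). The
hydrogen-bond test uses common geometric practice — O(i)···N(i+4) ≤
3.5 Å, C=O···N angle ≥ 90°, and, when the amide hydrogen exists (not
Pro), N–H···O ≥ 120° with the H built geometrically — because crystal
structures carry no hydrogens and no energy criterion is warranted at
this resolution.

Alternate locations are resolved deterministically (highest occupancy,
ties to the alphabetically first tag) so that torsions are reproducible
across reads. Entries without resolution metadata (NMR ensembles) are
excluded by the default 2.4 Å resolution filter; synthetic structures
carry a nominal 1.5 Å so they pass it.

## Torsions, rotamers and turn typing

Torsions follow the IUPAC sign convention; `dihedral()` is
property-tested against an independent normal-vector formulation to
1e-6°. χ1 rotamers are binned as g+ `[0°, 120°)`, g− `(−120°, 0°)`,
trans otherwise — boundaries chosen once so that the conventional labels
of all reference values (72° g+, 93° g+, 179°/−175° trans, −58° g−) are
reproduced; the underlying survey never states its bin edges.

The right-handed α-turn subtype is assigned when all six interior
backbone torsions fall within ±40° (circular difference, configurable)
of the template `(−59, −37, −65, −47, −79, −21)` — the largest-cluster
mean of the reference population. One caveat is documented rather than
hidden: the fourth reference cluster's ψ(i+3) mean (78°) lies ~99° from
the template value, so no single ±40° window admits all four cluster
means; cluster 4 classifies as `other` under the default tolerance.

## Clustering

Motifs are compared by least-squares (Kabsch) superposition on a fixed
**18-atom subset** — backbone N/Cα/C of the five residues, Cys Sγ, His
Nδ1, and the zinc — then partitioned by the **GROMOS neighbor-count
algorithm**: repeatedly take the element with the most neighbors within
the 0.4 Å cutoff as a centroid, remove it with its neighbors, and
report singletons as outliers. Ties break to the lowest input index,
making runs reproducible where the original implementation depended on
input order. The exact atom subset of the original survey is in
unpublished supplementary material; this reconstruction spans backbone,
both coordinating side chains and the metal, and every function accepts
a custom subset. Per-cluster torsion summaries use circular means and
circular SDs throughout — naive averaging of angles near ±180° would be
wrong by construction.

## C2 dimers and chirality

Two five-residue zinc-binding segments sharing one metal form a
*pseudo-symmetric pair* when their coordinating residues occupy the same
χ1 rotamer wells. `idealize_c2()` fits the rigid transform between the
segments (backbone + Cβ + coordinating atoms), projects its rotation to
exactly 180° about the fitted axis translated through the zinc, and
regenerates chain B as the exact symmetry copy — so the output is
C2-exact to machine precision while staying as close as possible to the
observed pair (pairs with fit RMSD > 2.5 Å are refused).

`build_c2_dimer_from_motif()` completes a *single* motif into a
tetrahedral S₂N₂ site by choosing the two-fold axis through the zinc
that minimizes the tetrahedricity score (mean |angle − 109.47°| over the
six donor–Zn–donor angles; 2° grid plus Nelder–Mead refinement). This
completion generically has **two** near-degenerate mirror solutions —
one Λ, one Δ. By default the sterically more open dimer is returned;
`chirality = "Lambda"` (or `"Delta"`) selects a handedness explicitly,
which is the right control when a model must reproduce the
configuration observed in natural dimers. On bare five-residue
fragments the steric tie-break does not systematically prefer Λ: that
preference in real structures arises from protein context the fragment
does not carry, so the package reports what the geometry supports
instead of forcing the expected label.

Λ/Δ itself is computed by the standard skew-line (two-blade propeller)
convention from the two donor-pair axes: a left-handed twist — negative
triple product — is Λ. Reflection of any site provably flips the label.

Hydrogens needed for NOE-style distance reports are built from standard
geometry (ring Hε1 on the Nδ1–Cε1–Nε2 external bisector at 1.08 Å;
amide H in the peptide plane at 1.01 Å, anti to the preceding carbonyl),
since experimental structures lack them.

## The binding model

Self-assembly of n peptide chains around one metal is written with the
dissociation constant on the fractional-power scale

K_D = [M]¹ᐟⁿ [P] / [MPₙ]¹ᐟⁿ,

which collapses dimensionally to molar and is the scale on which the
micromolar constants of the experimental literature are quoted (n = 2
throughout the default designs). Mass balances reduce the speciation to
a monotone scalar equation in free peptide, solved by bracketed root
finding to ~1e-15 relative — mass conservation is asserted to 1e-9 in
tests. Competition between two metals uses the exchange constant K_ex
with the identity **K_D(2) = K_D(1)/K_ex^(1/n)**, which holds
algebraically between the two parameterizations and is asserted
numerically to 1e-12.

Fitting minimizes unweighted squared error in the saturation fraction
Y = n[MPₙ]/P_t (the observable plotted in titration experiments;
converting absorbance to Y is the caller's responsibility). K_D and
K_ex are log-parameterized for positivity; standard errors come from
the numerical Jacobian at the optimum, with the delta method through
the log. The stoichiometry can be fitted as a continuous parameter and
is reported alongside its rounded value. The pH transition uses a
two-state sigmoid with a Hill slope — a documented modelling assumption,
as no functional form is standard for this measurement.

## What the synthetic generator emulates — and what it does not

`build_motif_structure()` constructs peptides residue-by-residue from
canonical internal geometry (Engh–Huber-type backbone values, ideal
imidazole ring, ω = 180°, L-configuration fixed by the +120° N–C–Cα–Cβ
improper) at prescribed φ/ψ/χ1. For an ideal zinc, the His ring
rotation (χ2) is tuned so the Sγ–Nδ1 separation matches a tetrahedral
S/N site, and the metal is placed at the exact intersection of the
2.34 Å and 2.05 Å donor spheres, on the side facing away from the
peptide body (a smooth, deterministic choice, falling back to a
clearance-maximizing point in crowded pockets).

`make_benchmark_set()` emulates the reference population: clusters of
86/16/13/11 members plus three singletons, members jittered around the
cluster-mean torsions. The jitter (2.5° per angle, plus 0.02 Å
coordinate noise) is calibrated so the emulated within-cluster spread
matches the published one — overall mean pairwise RMSD ≈ 0.55 Å against
the reported 0.5 Å, centroid-to-member distances ≲ 0.3 Å. Terminal
torsions are not part of the published cluster table; ψ of residue *i*
defaults to 120° (extended entry into the turn), the regime in which
the two donors converge on a common metal position in every cluster.

What passing tests on this material do **not** show: recovery of the
exact published database counts (129 motifs / 44 unique sequences
depend on a specific PDB snapshot and identity culling, and are treated
as population parameters of the generator, not as rediscoverable
facts); real crystallographic disorder, correlated torsion variation,
alternate tautomers, or crystal packing; and the protein-context
effects that bias natural dimers toward the Λ configuration. Distances
measured on reconstructed dimers (e.g. the inter-chain Hε1···HN
contact) inherit the uncertainty of the unconstrained terminal torsions
and ring orientation, of order 1 Å.

The propensity background is a bundled Swiss-Prot average composition,
clearly labelled in every output; the original survey's background
table is not published, so propensities reproduce it only approximately
and are deliberately not tuned to match.

## Numerical choices

* Root finding: `uniroot` with machine-precision tolerances on brackets
  that provably contain the unique root (speciation is monotone).
* Optimization: Nelder–Mead then BFGS for multi-parameter fits; axis
  searches use a 2° grid to localize basins before local refinement.
* Karplus inversion: 0.25° grid with sign-change refinement plus
  tangential-touch detection, returning all φ with |J(φ) − J| ≤ 0.05 Hz.
* Tie-breaks (clustering ties, altloc ties, enantiomeric axis ties) are
  all deterministic and documented above.
* Degenerate inputs error early with named atoms/residues: collinear
  torsion quadruples, rank-deficient superpositions, sub-4-coordinate
  site-geometry requests, unbracketed pH transitions.

## Problem sizes

The bundled tests run the full 129-member benchmark once (about 15 s),
500 randomized small instances of the clustering oracle comparison, 200
seeded titration-recovery replicates, and 1000 random torsion quadruples
against the dihedral oracle — sizes chosen to exercise every code path
at interactive turnaround on a single core.

## Known limitations

* The mmCIF reader handles crystallographic `_atom_site` tables (one
  model); multi-model NMR mmCIF depositions keep only the first model.
* `sequences_from_occurrences()` realizes a sequence set from marginal
  counts; it reproduces column statistics, not the (unpublished) actual
  sequence list.
* Peptide building covers backbone, Cβ, and full Cys/His side chains;
  other side chains are truncated at Cβ, which is sufficient for the
  18-atom clustering subset but not for all-atom contact analysis.
* The binding solver assumes a single n:1 complex per metal; mixed or
  partially-ligated intermediates are outside the model.
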