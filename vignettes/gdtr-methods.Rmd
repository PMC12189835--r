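---
title: "Models and methods behind gdtr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gdtr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdtr)
```

# Scope and scientific setting

`gdtr` analyses gamma–delta T cell receptor (TRG_TRD) heterodimers and
their complexes with the lipid-presenting MH1-like molecule CD1D and its
light chain B2M. In gamma–delta-high species such as the dromedary, the
delta chain's third complementarity-determining region (CDR3) is
diversified by rearrangements that incorporate several TRDD segments,
producing loops of up to roughly 37 amino acids. Comparing such receptors
across clones, species and structures requires a common positional
coordinate system (the IMGT unique numbering), a reproducible junction
decomposition, and geometric rules for reading protein–protein interfaces.
This vignette records the models implemented, the defaults chosen, and the
boundaries of what the shipped tests demonstrate.

# The IMGT position system

V domains are numbered 1–128 with fixed region boundaries: FR1 1–26,
CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104, CDR3 105–117, FR4 118–128.
Four anchors pin the frame: the 1st-CYS at 23, the conserved TRP at 41,
the 2nd-CYS at 104, and J-PHE/J-TRP at 118 (the F/W of the J-MOTIF
F/W–G–X–G). CDRs shorter than their spans are gapped centre-out — the gap
sits at the top of the loop — so, e.g., a 6-residue CDR1 occupies
27–29 and 36–38. CDR3 loops longer than 13 residues gain numeric
insertion positions between 111 and 112, filled alternately starting on
the 111 side (111.1, 112.1, 111.2, ...), the 111 side taking the larger
share when the count is odd. The resulting order is total and asymmetric
around the loop apex: insertions ascend after 111 and descend into 112
(111 < 111.1 < ... < 112.2 < 112.1 < 112). `imgt_position_key()` realises
this order as a numeric sort key; property tests check it against a
hand-enumerated oracle and check the occupancy/insertion count for every
CDR3 length from 1 to 40.

G (platform) domains are numbered 1–92, positions 1–49 forming the
four-strand floor and 50–92 the helix. Queries are numbered by global
alignment to a shipped reference scaffold; query residues inserted
relative to the reference become letter positions (72A, 72B, ...)
attached to the preceding numbered position. An alignment covering less
than half the reference is rejected as "not a G-domain".

**Anchor detection.** Queries are first aligned (global, BLOSUM62,
gap 10/0.5) to the shipped full-length scaffolds; the aligned images of
positions 23/41/104 seed a ±5 search window for the expected residue
class, and 118 is the first F/W–G–X–G downstream of the 2nd-CYS. Explicit
anchor hints bypass detection, which also makes the numbering invariant
to flanking sequence. FR2 and FR3 are treated as fixed-length (17 and 39
residues); V domains with indels inside frameworks are out of scope and
rejected rather than misnumbered.

# Junction decomposition

The CDR3-IMGT of a rearranged clone runs from codon 105 (the codon after
the 2nd-CYS codon 104) to codon 117 (the codon before J-PHE/TRP 118).
Within the junction nucleotides, the 3'V contribution is the maximal
exact prefix shared with the germline V beyond its 2nd-CYS codon and the
5'J contribution the maximal exact suffix shared with the germline J
before its J-PHE/TRP codon. The remainder is scanned for germline D
segments: un-gapped matches of at least `min_match = 5` nt with at most
`max_mismatch = 1` substitution, required to start and end on a matching
nucleotide. Overlaps are resolved by selecting the longest match, then
the fewest mismatches, then the leftmost start, then the
lexicographically smallest gene name; after each acceptance the remaining
free stretches are re-scanned, which makes the greedy result identical to
exhaustive window enumeration (verified against a brute-force oracle on
random junctions up to 60 nt). Unattributed stretches are reported
jointly as PN: distinguishing P- from N-nucleotides would require
germline ends plus a palindrome test that the decomposition itself does
not need. Both thresholds are exposed as arguments.

With these thresholds, random non-templated stretches of five or more
nucleotides can match some D segment by chance — an identifiability limit
of the method, not an implementation artifact. The clone generator
therefore keeps its default PN stretches at 0–4 nt and rejects draws
whose planted composition is not the one the attribution rules recover,
so that generator truth is always well-defined.

# Template threading, superposition, clashes

`thread_model()` is deliberately minimal comparative modelling: backbone
atoms (N, CA, C, O) are copied from the template for every aligned pair;
side chains are retained only for identical residues, otherwise truncated
to CB (an ideal tetrahedral CB is built when the template lacks one);
query insertions are flagged, never rebuilt — a rebuilt loop would be
invented geometry, and downstream contact analysis tolerates the gaps.
There is no rotamer optimisation, loop closure or minimisation. A
consequence worth recording: threading a sequence onto its own structure
is exactly coordinate-identical, so model-vs-template RMSD is ~0 by
construction; published model RMSD values of a few tenths of an Ångström
reflect post-processing by external minimisation servers and are
documented as not reproducible with threading alone.

`superpose()` implements the Kabsch least-squares rigid superposition via
SVD with the determinant correction that guarantees a proper rotation;
degenerate (rank < 2) point sets are rejected. Tests require zero
self-RMSD, exact recovery of known transforms to 1e-6, invariance to
rigid pre-transforms, and agreement with an independent least-squares
implementation on noisy data. `clash_count()` counts heavy-atom pairs
from different residues closer than 2.2 Å, excluding backbone contacts of
sequence-adjacent residues — a simple stand-in for a full clash score.

# Interface interaction typing

Residue pairs between two chain groups are classified on heavy-atom
geometry (hydrogens, if present, are ignored; threaded models have none,
which is also why hydrogen bonds carry no angle term):

| type | rule | threshold (Å) |
|---|---|---|
| IONIC | opposite formally charged side-chain atoms | ≤ 6.0 |
| HBOND_SS / MS / MM | donor–acceptor heavy atoms, subtyped by main/side membership | ≤ 3.5 |
| AROMATIC_AROMATIC | ring centroid–centroid | 4.5 – 7.0 (inclusive) |
| AROMATIC_SULFUR | ring centroid to Cys SG / Met SD | ≤ 5.3 |
| CATION_PI | ring centroid to Lys NZ / Arg guanidinium N | ≤ 6.0 |
| HYDROPHOBIC | side-chain carbon pair, both residues apolar | ≤ 5.0 |

"Within X Å" is read as ≤ X, and the aromatic window is inclusive at both
ends. Histidine counts both as potentially cationic (ionic partner) and
as aromatic. One contact is kept per (residue pair, type) at the minimal
defining distance, and every emitted table re-validates its distance
windows. All six thresholds are exposed via `contact_params()`. Where
sources disagree on the aromatic lower bound (4.4 vs 4.5 Å), 4.5 is
adopted. The planted-geometry generator builds each class at an exact
requested defining distance (side chains opposed, backbones pointing
away), and the test sweep confirms labels flip exactly at each threshold.

# The interface energy model

`interaction_energy()` follows the unfold-and-subtract scheme:
ΔG_int = E(complex) − [E(A) + E(B)]. Because every term is a pairwise
atom–atom sum, intra-group contributions cancel exactly and ΔG_int equals
the inter-group pairwise sum; the identity is asserted numerically on
every call and cross-checked against an explicit unfold-and-subtract
evaluation in the tests. Terms:

- **van der Waals**: Lennard-Jones 6-12 on heavy atoms with a small
  per-element united-atom parameter set (rmin 1.7–2.0 Å, well depths
  0.12–0.25 kcal/mol), truncated beyond 12 Å; repulsion is capped below
  1 Å (with a warning) so output stays finite.
- **electrostatics**: Coulomb with distance-dependent dielectric
  ε(r) = 4r over formal charges on Asp/Glu/Lys/Arg side-chain groups.
- **hydrogen bonds**: a −1 kcal/mol well for donor–acceptor heavy-atom
  pairs between 2.2 and 3.5 Å, linearly tapered near the cutoff.
- **desolvation**: −0.03 kcal/mol per buried nonpolar carbon–carbon
  contact within 5 Å.

Entropic contributions are omitted. The model's contract is the sign
convention (more negative = stronger binding), the infinite-separation
limit, rigid-transform invariance, conservation of the per-term and
per-residue decomposition, and the strict improvement from planting a
favourable contact — not numeric agreement with any published force-field
energy. Published kcal/mol values are used in this package only as
ordering fixtures for `rank_complexes()`.

# Synthetic data: what it emulates and what it does not

All fixtures are generated in code with full truth records; files shipped
under `inst/extdata` are synthetic and labelled as such in their names.
The V/G scaffolds carry the conserved anchors at canonical spacings; the
hallmark fixtures reproduce published features — CDR lengths [6.8.15] and
[7.3.37], the hallmark residues at their IMGT positions, the CD1D 72A
serine insertion, TRDD1/D2/D4/D5 usage at CDR3 length 37 — without
containing any database sequence. The clone generator emits productive,
in-frame junctions and rejects draws that would fake an anchor (a chance
Cys or J-motif inside the junction) or an ambiguous D composition; its
germline D set avoids stop and Cys codons in every reading phase so that
rejections stay cheap. Two-chain interaction fixtures realise each
interaction class at an exact defining distance, with decoy residues at
least 10 Å away; the four-chain toy complex scatters planted contacts on
a non-collinear lattice 20+ Å apart.

What passing these tests shows: the numbering, decomposition,
classification and energy machinery are internally correct against
independent oracles and exact planted truth. What they do not show:
performance on real cDNA with somatic hypermutation outside D segments,
real crystal-structure geometry (solvent, alternate conformers beyond
simple altloc resolution, lipid ligands), or force-field-grade
energetics. Real-data claims require the corresponding database
sequences and deposited coordinates, which are deliberately not bundled.

# Numerical and design choices

- Alternate locations resolve to the highest occupancy, ties by altloc
  letter; author numbering and insertion codes are preserved verbatim.
- Global alignment defaults: BLOSUM62, gap open 10, extend 0.5; recorded
  in every alignment object's `params`.
- Generator seeds: one integer seed drives one named stream per
  generator (offset by a hash of the generator name), so adding a
  generator never shifts another's draws; the same seed reproduces
  byte-identical output.
- Problem sizes in the shipped tests — 100-clone recovery runs, 50-case
  oracle comparisons, 12–30-residue chains — were chosen as the smallest
  sizes at which every property is exercised with non-trivial variety.
- Degenerate inputs fail loudly and early: empty chain groups,
  non-disjoint groups, collinear superposition sets, unlocatable anchors
  and frame-breaking junctions are errors, not silent results.

# Known limitations

- Framework indels in V domains are rejected rather than numbered; the
  G-domain letter-insertion inventory follows the shipped reference
  scaffold, whose choices are its own documentation.
- The D-attribution thresholds cannot distinguish chance matches inside
  long non-templated stretches from true short D remnants (see above).
- `superpose()` pairs residues by sequence correspondence; a pure
  structure-based pairing search is out of scope.
- The energy model is not calibrated to experiment; only its qualitative
  contracts are meaningful.
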