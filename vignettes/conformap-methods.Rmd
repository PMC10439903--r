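---
title: "Methods: CDR-H3 conformation classification and repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDR-H3 conformation classification and repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformap)
```

## The problem

Camelid heavy-chain-only antibodies bind antigen through a single variable
domain (VHH, nanobody). Without a light-chain partner, the third
complementarity-determining region (CDR-H3) explores a much larger
conformational space than in conventional antibodies, and falls into two
broad families: *kinked* loops that fold back over framework 2 (FWR2, the
former light-chain interface), and *extended* loops that protrude into
solvent. The two families differ in loop length, FWR2 packing, secondary
structure at the loop stem, and how the domain engages antigen. `conformap`
implements the structural side of this analysis (stem-angle classification,
contact maps, solvent accessibility, paratope accounting) and the
repertoire-sequencing side (UMI consensus, V(D)J junction annotation,
isotype assignment), together with synthetic generators that make every
step testable without external data.

## Stem-angle classification

The C-terminal stem of CDR-H3 is summarised by two angles over C-alpha
atoms:

* `tau101` — the planar angle at Chothia position 101 over the triple
  (100x, 101, 102), where *100x* denotes the residue immediately preceding
  101 in chain order (the last CDR-H3 insertion, whatever its insertion
  code);
* `alpha101` — the signed pseudo-dihedral over the four chain-order stem
  residues ending at 102 (the residue before 100x, 100x, 101, 102), IUPAC
  sign convention (cis = 0).

`tau101` is sometimes described loosely as a pseudo *dihedral*, but three
points define a bond angle, not a torsion; the observed 85–145° range is
only meaningful under the planar reading, which is the one implemented
(`pseudo_bond_angle()`). The classification windows are

* kinked: `0 < alpha101 < 120` and `85 < tau101 < 130`;
* extended: `alpha101 < -100` and `100 < tau101 < 145`;
* everything else: `other`.

All inequalities are strict. Whether boundary values belong to a window is
immaterial at dataset scale (the windows are separated by wide `other`
bands), but strictness makes the partition property exactly testable: the
two windows are disjoint on an exhaustive 0.5° grid.

```{r}
classify_h3(60, 110)
classify_h3(-120, 120)
classify_h3(0, 110)   # boundary -> other
```

Both angle routines are validated against independently derived formulas
(arccos of the normalised dot product; the projection form of the torsion)
and against rigid-motion invariance and reflection antisymmetry on random
inputs.

## Regions, insert numbering and contact maps

Chothia intervals partition positions 1–113: FWR1 1–25, CDR1 26–32,
FWR2 33–51, CDR2 52–56, FWR3 57–94, CDR3 95–102, FWR4 103–113.
Insertion-coded residues inherit the region of their base number, the
standard Chothia practice.

Because the stem conformation is a C-terminal property, CDR-H3 residues in
contact maps are numbered backward from the stem: insert position I1 is
100x, I2 the residue before it, and so on toward position 95 (at most I21).
Two residues are in contact when any heavy-atom pair is **4.0 Å or less**
apart — the cutoff is inclusive, and all non-hydrogen atoms (backbone and
side chain) participate, which is the reading that captures the
aromatic-stacking interactions characteristic of kinked loops. Cohort maps
report, per (FWR2 position, CDR-H3 column), the fraction of structures in
contact; structures lacking a column position (short loops) are excluded
from that column's denominator so loop-length artefacts cannot masquerade
as absent contacts. Position frequency matrices over the same residues
accompany the map in place of rendered logos.

## Solvent accessibility and paratope areas

`shrake_rupley()` samples each atom's expanded sphere (van der Waals radius
plus a 1.4 Å water probe) at quasi-uniform Fibonacci-spiral points (960 by
default) and counts the points outside all neighbouring expanded spheres.
The default radii are the classic protein-crystallography set (C 1.87,
N 1.65, O 1.40, S 1.85 Å); relative accessibility divides residue SASA by
the Miller Gly-X-Gly standard-state maxima, which were derived with those
same radii, so a fully exposed alanine in an extended Gly-Ala-Gly
tripeptide scores ≈ 1. A Bondi element set and custom radii are available
where a different convention is needed; the isolated-atom closed form
4π(r + probe)² and the two-sphere spherical-cap formula hold to well under
1% and 2% respectively at the default sampling.

Paratope accounting treats all antigen chains as one antigen. A region is
*used* when any of its residues contacts any antigen atom (same inclusive
4.0 Å rule); its *buried area* is the sum over its residues of
SASA(VHH alone) − SASA(VHH in complex), with negative per-residue
differences clamped to zero (sampling noise). ΔSASA on complex formation is
the standard SASA-based definition of interface area; the total paratope
area is, by construction, exactly the sum of the region areas.

## Secondary structure

Secondary structure is assigned by a Kabsch–Sander style hydrogen-bond
analysis over backbone N, CA, C, O: amide hydrogens are rebuilt from
peptide geometry, the electrostatic bond energy is
`0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332` kcal/mol with bonds below
−0.5 kcal/mol, and only the simplified alphabet {G, H, T, E, C} is emitted
(consecutive n→n+3 turns give G, n→n+4 give H, isolated turns T, bridge
ladders E). Full 8-state fidelity is out of scope because only the
3-10-helix/turn distinction at insert positions I2–I4 (`stem_motif()`) is
consumed downstream. Ideal-geometry fragments built from canonical
dihedrals (3-10: φ=−49°, ψ=−26°; alpha: φ=−57°, ψ=−47°; extended:
φ=ψ=180°) provide the reference cases.

Predicted structure models carry per-residue confidence (pLDDT, 0–100) in
the B-factor column; a model is dropped when confidence at any of 100x,
101, 102 is strictly below 70 — at exactly 70 the model is kept.

## Repertoire pipeline

Reads derive from a 5' RACE library whose template-switch adapter embeds a
12-nt UMI as three N-quadruplets between fixed (deoxy-U, read as T) bases.
The pipeline:

1. **UMI extraction** — the adapter pattern is matched exactly (no
   mismatch allowance — reads with PCR/sequencing errors in the fixed
   pattern are better discarded than rescued, and spurious UMI variants are
   caught by the frequency filter); reads with zero or multiple occurrences
   are rejected but counted.
2. **Frequency filter** — UMI groups below 10 reads are dropped. The
   protocol description and the summary table disagree on this threshold
   (less-than-9 discarded vs frequency ≥ 10); the table's ≥10 is the
   default and the value is configurable.
3. **Consensus** — per-column plurality, separately for the two mates,
   read 1 anchored at the adapter end (absorbing the variable 1–4 nt
   primer overhang); ties give N. Base qualities are not used — plurality
   over ≥10 reads already drives per-column error odds far below any
   quality-weighting gain.
4. **Merging** — best ungapped overlap of the reverse-complemented mate-2
   consensus against mate 1 (≥10 nt, ≤25% mismatches, score = matches −
   mismatches, ties to the longer overlap); disagreements resolve toward
   the column with higher consensus support.
5. **V/D/J assignment** — best local alignment (match +1, mismatch −2, gap
   open −5, extend −2) against the V and J references; the V trim position
   is the last reference position covered, the J trim position the first.
   D is sought only inside the V–J junction window and requires a
   contiguous exact match of ≥5 nt (ties: longer, then 5'-most). The
   scoring and the 5-nt floor are this package's choices — the original
   analysis delegated to an external aligner — and are validated by exact
   truth-table recovery on simulations.
6. **Junction metrics** — `np_d_length` counts nucleotides strictly
   between the trimmed V and J; CDR-H3 runs from 3 codons after the
   conserved framework-3 cysteine to the residue before the conserved
   Trp-Gly of framework 4; a record is in frame when the V-start→J-end
   stretch is divisible by 3 and free of internal stops.
7. **Isotype** — exact, case-insensitive substring match against the four
   llama hinge signatures; zero or ambiguous hits give `unassigned`.

Trim coordinates are 1-based within each germline segment; all internal
sequence indexing is 0-based half-open.

## Synthetic data: what it emulates, what it does not

The structure generator lays framework C-alphas on an idealised serpentine
grid (3.8 Å spacing, 12 Å row separation) with compact backbone satellites,
builds the four stem C-alphas to exact target angles
(`build_stem_coordinates()`, consecutive distances 3.8 Å), and routes the
loop either down onto FWR2 — placing I1 at a designed 3.5 Å stacking
distance above position 45 — or into solvent with ≥6 Å clearance from all
FWR2 atoms. Default designed loop lengths are 12 (kinked) and 9 (extended),
the means of the two structural families. The scaffold is *not* a folded
immunoglobulin: consumers measure distances and angles, never energetics,
so geometric truth is sufficient. Passing tests therefore demonstrate
correct geometry, bookkeeping and statistics on controlled input — not
robustness to crystallographic noise, alternate numbering dialects or real
loop ensembles.

The repertoire simulator assembles each molecule as adapter(UMI) + leader +
trimmed V + N/P + trimmed D + N/P + trimmed J + hinge + constant primer
site, and emits asymmetric read pairs (400 + 100 nt, matching the
sequencing design) with independent substitution errors. Distribution
defaults: V trimmed in codon steps by a truncated geometric (the observed
trim positions sit at codon boundaries), J trim 5–12 nt, D trims truncated
geometric with ≥8 nt retained, N additions Poisson(4) per side. Three
design features keep the designed truth identifiable: junction bases are
resampled when their first/last three bases would elementwise extend the
flanking germline match; junctions whose translation would contain a
premature Trp-Gly anchor (or, for in-frame molecules, a stop) are redrawn;
and amplicons are capped at 490 nt, mirroring the gel size-selection step
of the protocol and guaranteeing the mates overlap. Molecules are built in
frame by default (expressed, isotype-switched B-cell receptors are
productive); the flag is configurable for funnel studies. Indels,
quality-score structure and somatic hypermutation are not modelled.

## Numerical choices and degenerate inputs

* Angle routines use `atan2` forms (stable near 0°/180°); coincident or
  collinear points are hard errors.
* Superposition RMSD uses the Kabsch SVD solution with a determinant
  correction against reflections; fewer than 3 common positions is an
  error.
* Alternate PDB locations resolve to the highest occupancy (ties: first
  listed); hydrogens are dropped on parsing; a CDR-H3 residue lacking its
  C-alpha flags the chain unclassifiable rather than silently skipping.
* Exact Wilcoxon enumeration applies up to n = 12 without ties, the
  tie-corrected continuity-corrected normal approximation otherwise
  (delegated to `stats::wilcox.test`); chi-squared uses no continuity
  correction; Holm is the default multiplicity adjustment, chosen as the
  conventional default where the original analysis does not name a method,
  with Bonferroni available.

## Problem sizes

The shipped tests and the acceptance script run desk-scale versions of
each analysis: 50-structure cohorts (30 kinked / 20 extended), 8-structure
contact-map cohorts, 4 toy complexes at 240 sphere points, and repertoire
simulations of 100–150 molecules at 12 reads per UMI. These sizes were
chosen so the designed effects are exactly recoverable while a full run
stays in the minutes range on one core; all generators scale to larger
cohorts by argument.

## Known limitations

* Input structures must already carry Chothia numbering (SAbDab dialect);
  renumbering from raw sequence is out of scope.
* mmCIF is not supported; VHH chains are named explicitly rather than
  auto-detected.
* The D-segment caller requires an exact ≥5-nt match and will return
  no call for heavily mutated or very short retained D segments.
* The secondary-structure assignment targets the G/H/T/E/C distinctions
  only and is not a drop-in replacement for full DSSP output.
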