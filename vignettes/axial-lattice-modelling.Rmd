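---
title: "Helical lattice modelling of flagellar axial structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical lattice modelling of flagellar axial structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axialkit)
```

## The model

Flagellar axial proteins (FlgG in the distal rod, FlgE in the hook, FliC in
the filament) assemble on a common helical lattice. The lattice is defined
by a screw generator: subunit $n{+}1$ is subunit $n$ rotated by the twist
$\theta$ about the helix axis and translated by the rise $z$ along it. A
subunit at lattice index $n$ therefore carries the transform

$$ x \mapsto R_z(n\theta)\,x + (0, 0, nz)^\top, $$

computed in closed form (`lattice_transform()`), which agrees with the
$n$-fold composition of the generator to floating-point round-off — a
property the test suite asserts as the group law.

Three derived quantities describe the lattice the way the field talks about
it:

* **Subunits per turns.** The number of subunits in $t$ turns of the 1-start
  helix is $\mathrm{round}(360t/\theta)$. At the rod twist of 64.75° this
  gives 11 subunits per two turns and 22 per four turns; nearest-integer
  rounding is the convention that matches both printed counts
  simultaneously.
* **Protofilament count.** Protofilaments are the near-axial strands: the
  offset $n$ whose cumulative rotation $n\theta$ is closest to a whole
  number of turns. `protofilament_count()` scans $n = 2..30$ and minimizes
  the residual wrapped to $(-180°, 180°]$; at 64.75° the winner is $n = 11$
  with residual $-7.75°$. The bound of 30 is a physical choice — lattice
  families beyond that have no structural meaning at this scale — and ties
  are reported in full with the smallest offset returned.
* **$n$-start families.** For an offset $k$, the net rotation and rise
  between subunits $n$ and $n{+}k$ classify the interaction direction:
  $k = \pm 5$ (5-start), $\pm 6$ (6-start), $\pm 11$ (protofilament).

### Sign and handedness conventions

The working frame puts the helix axis on $z$ with the distal direction at
$+z$; positive twist is a right-handed screw about $+z$. Offset $-5$ means
the subunit five positions *proximal* along the 1-start helix, which is the
convention in which the rod l-stretch network is described (it contacts the
D1 domains of the subunits at $-5$, $-10$, $-11$ and $-16$; the hook's at
$-5$ and $-11$ only). Published descriptions of this lattice do not state
handedness explicitly, so it is a constructor flag (`handedness`), with
right-handed as the default that makes those neighbor labels reproduce
directly.

## Symmetry inference

`infer_symmetry()` inverts assembly construction: for each consecutive pair
of subunits it fits the least-squares rigid transform (Kabsch), decomposes
it as a screw motion (rotation angle about the fitted axis → twist, axial
component of the translation → rise), and averages over steps. Two residuals
are reported and matter for different failure modes:

* the per-step superposition RMSD, which catches deformed or non-helical
  coordinates;
* the per-step *parameter spread* (standard deviation of step twists and
  rises), which catches a broken subunit order. This one is essential:
  the subunits of a perfect assembly are congruent, so any permutation of
  them still superposes pairwise at RMSD ≈ 0, and only the wildly
  inconsistent step parameters reveal the shuffle.

On noiseless assemblies the recovery is exact to ~1e-12 relative; with
0.2 Å Gaussian coordinate noise on a 22-subunit assembly the twist is
recovered within 0.1° and the rise within 0.05 Å (tolerances chosen from
the spread of repeated seeded runs, asserted in the suite).

## Superposition and RMSD

`kabsch()` implements the SVD solution for the proper rotation minimizing
RMSD, with the reflection branch corrected by the determinant sign. The
returned transform moves the *first* argument onto the second, mirroring
the phrasing "the donor was superimposed on the acceptor". Collinear point
sets (second singular value ≈ 0) are an error, not a silent pseudo-inverse.
Chain comparisons default to Cα atoms — the convention in which such RMSDs
are reported (the FlgG20 crystal dimer chains agree at 0.60 Å) — with
all-heavy-atom fitting behind `atom_name = NULL`. There is deliberately no
outlier trimming or iterative rejection: published plain RMSDs are plain
RMSDs, and trimming would make the number convention-dependent.

Optimality is tested against a brute-force oracle: on random ≤ 20-point
instances the fitted RMSD must not exceed the RMSD under any of 10,000
uniformly sampled rotations.

## Grafting

Chimeric subunit models are built the way full-length rod/hook subunits
were modelled from a crystal fragment plus a homolog: superpose the donor
on the acceptor by a shared domain (default D1, Cα atoms, paired by rank
within the segment), rigidly transfer the chosen donor segments (D0
helices, l-stretch), and relabel the transferred residues to the target
sequence. Design choices:

* **Sidechain "replacement" is relabel + truncate, not rotamer building.**
  Each transferred residue takes the target residue type and keeps exactly
  the atoms shared between old and new type (backbone always kept; TRP→SER
  keeps backbone + CB). This is deterministic and testable; real geometry
  repair belongs to downstream refinement, which is out of scope here.
* **Junctions are reported, not repaired.** No peptide-bond regularization
  at splice points.
* **Missing density is an explicit deletion mask.** The l-stretch tip
  (residues 53–64 in FlgG, 12 residues) is removed by
  `apply_deletion_mask()`, preserving the numbering gap — never
  interpolated.
* **Acceptor preservation is bit-exact** outside the grafted ranges, and a
  grafted segment's internal distance matrix equals the donor's to 1e-6
  (rigid transfer); both are asserted in the suite.

Default segment boundaries for FlgG (D0N 1–46, l-stretch 47–84, D1 85–221,
D0C 222–260) are inferred from the crystallized core-fragment construct
(residues 47–227) and the terminal β-stretch landmarks (85–89 / 218–221);
exact l-stretch boundaries are not stated numerically anywhere, so all
boundaries are configuration, never constants.

## Contact networks

`contact_map()` enumerates heavy-atom inter-subunit pairs within a cutoff
using a cell-list grid (cell size = cutoff), aggregates them per
(subunit pair, segment pair), and labels every edge with its lattice
offset. The grid is tested for exact edge-multiset equality against an
all-pairs $O(N^2)$ oracle, and the edge set is monotone in the cutoff and
symmetric by construction.

"Interacts" means ≥ 1 heavy-atom pair within the cutoff (a stricter
`min_pairs` is a parameter). The default cutoff is 4.0 Å, a typical van
der Waals contact criterion; the original interaction descriptions state
no cutoff, so `fingerprint_sensitivity()` reports fingerprints at
3.5/4.0/4.5 Å in the standard report to expose the sensitivity. On the
synthetic rod-geometry assembly the designed arm fingerprint is identical
at all three cutoffs.

`segment_fingerprint()` requires the reference subunit to be *interior*:
every neighbor as far away as the largest observed contact offset must be
present, otherwise edge-of-assembly truncation silently shrinks the
fingerprint. The margin is derived from the data (max |offset| in the edge
table) and can be overridden.

For mutation-site mapping, sites absent from the model (e.g. inside the
53–64 mask) are flagged unmodeled and inherit the contact environment of
their nearest modeled flanking residues, explicitly marked approximate —
an honest envelope rather than a fabricated position. Note one source
discrepancy the package does not attempt to resolve: the hook l-stretch
network is described in one place as touching $-5$/$-11$ and elsewhere as
$-5$/$-10$; the package's tests adopt the detailed contact description
($-5$, $-11$, not $-10$, not $-16$).

## Sequence alignment

`global_align()` is Needleman–Wunsch with affine gaps (engine: Biostrings),
defaulting to BLOSUM62 with gap open 10 / extend 0.5 — EMBOSS-needle-style
settings, the style under which FlgG vs FlgE aligns at ≈ 39% identity.
Identity is reported as identical pairs over aligned columns *excluding
terminal overhangs but including internal gaps*; the convention is embedded
in the result object because published percent identities rarely state
theirs. The DP score is verified against exhaustive alignment enumeration
on short sequences.

`structure_based_alignment()` pairs residues by mutual nearest Cα neighbors
within 3 Å after superposition, then enforces a monotone one-to-one pairing
by accepting candidates in order of increasing distance — the
longer-distance member of any crossing conflict loses, deterministically.

## The synthetic generator

`make_toy_subunit()` emulates the three architectural elements every stage
needs, at ~49 Cα atoms per subunit:

* an inner **D0** element: two antiparallel ideal helices (Cα rise 1.5 Å,
  100°/residue) near the axis;
* an extended **arm** (l-stretch analog): a straight Cα trace at 3.8 Å
  spacing from the D0 region toward the D1 centroid of the subunit at a
  chosen lattice offset, stopping 2.5 Å short of it — so in the built
  assembly the arm tip is within 3 Å of that neighbor's centroid atom and
  the designed contact is guaranteed at a 4 Å cutoff;
* a globular **D1** body: a deterministic Fibonacci-sphere shell (default
  radius 3 Å, centroid 30 Å from the axis) with small seeded jitter.

The defaults place the toy on the rod lattice (64.75°/4.13 Å) with the arm
aimed at −5, so synthetic tests mirror the distal-rod geometry. Generation
is fully deterministic for a fixed spec and seed. An arm shorter than the
required reach is an error stating the minimum; arm length 0 omits the arm.

What the toy does *not* emulate — and therefore what passing synthetic
tests do and do not show: there are no sidechains (contacts are Cα-level),
no realistic packing density (real subunits touch many neighbors through
many segments; the toy's arm touches exactly one), no conformational
variation between copies, and no D2 domain. Synthetic tests validate the
*machinery* (lattice algebra, contact enumeration, grafting bookkeeping,
estimator correctness); statements about real rod/hook contact networks
are validated only by the deposited-entry checks, which require downloads.

## Numerical choices

* Rotation orthonormality is enforced at 1e-9 on construction; composed
  transforms are re-validated at 1e-6 (round-off accumulates).
* Assemblies are built from closed-form transforms, not iterated
  composition, so index-22 placement error does not accumulate.
* PDB coordinates round-trip at the 1e-3 Å fixed-width field precision;
  the mmCIF writer emits full double precision and round-trips exactly.
  More than 62 chains cannot be written as PDB (one-character chain-id
  alphabet) — that is a hard error directing to mmCIF, never silent
  renaming.
* Alternate locations: the lexicographically smallest altloc id is kept,
  deterministically. Hydrogens are dropped on read (contact analysis is
  heavy-atom). Waters are HOH/WAT residues; other het groups are excluded
  from protein counts.
* Problem sizes in the test suite (22-subunit assemblies of ~49-atom
  subunits, ≤ 2,000-atom brute-force comparisons, 10,000-rotation
  optimality oracles, 50-draw parameter-recovery sweeps) keep the whole
  suite around ten seconds while still exercising every code path at the
  scale the published models use (22 subunits, four turns).

## Known limitations

* No crystallographic or EM refinement of any kind: no density-map I/O,
  no map fitting, no validation statistics. Grafted junctions have
  unregularized geometry by design.
* Contact fingerprints on deposited assemblies depend mildly on the
  cutoff; the sensitivity table is the honest report, not a single number.
* The residue-pairing used for grafting is rank-based within the aligned
  segment; homolog pairs with very different segment lengths should supply
  an explicit alignment instead.
* `infer_symmetry()` assumes a single 1-start screw relates consecutive
  subunits; polymorphic or curved (e.g. bent-hook) assemblies violate this
  and show up in the step-parameter spread rather than being modelled.
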