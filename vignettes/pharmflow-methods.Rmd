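---
title: "Methods: receptor-based pharmacophore screening and pose-consensus filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-based pharmacophore screening and pose-consensus filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmflow)
```

pharmflow implements a structure-based virtual-screening cascade of the kind
used to hunt for reversible inhibitors of serine hydrolases such as
monoacylglycerol lipase (MAGL): a receptor-based pharmacophore screen,
followed by interaction-based filtering of docking poses, cross-method pose
consensus, and a molecular-dynamics stability filter. The docking engines
and the MD engine themselves are out of scope - their outputs (poses, frames)
are inputs here. This vignette explains the models and the numerical choices;
the README shows the workflow end to end.

## The pharmacophore model

A model is a set of typed tolerance spheres plus excluded-volume spheres.
A feature has a kind (`HBA` hydrogen-bond acceptor, `HBD` donor, `HYD`
hydrophobic - the `HYD` kind also accepts aromatic-ring centroids), a center
in the receptor frame, a tolerance radius, and a mandatory flag. A ligand
*matches* a feature when a perceived feature point of a compatible kind lies
inside the sphere. All mandatory features must be matched; optional features
improve rank. A ligand heavy atom strictly inside any excluded-volume sphere
disqualifies the match.

`build_receptor_model()` derives a model from a bound complex:

* one HBA feature per ligand acceptor that is H-bonded to a protein donor or
  to a listed structural water, centered on the acceptor atom;
* one HYD feature per ligand hydrophobic/aromatic site backed by at least
  `min_apolar_contacts` (default 2) protein apolar heavy atoms within the
  hydrophobic cutoff, centered on the site centroid;
* excluded volumes on every protein heavy atom within `ev_shell`
  (default 6.0 Å) of any ligand heavy atom, excluding atoms that are H-bond
  partners of a feature (a sphere on the donor would forbid the very contact
  the feature encodes).

By default all HBA features plus the best-contacted HYD feature are
mandatory and the rest optional - the classical "all polar anchors plus the
dominant lipophilic pocket" recipe, which on the package's reference fixture
gives the canonical 4 HBA + 4 HYD model with a 5/3 mandatory/optional split.
For other systems the mandatory set can be overridden explicitly
(`model_config(mandatory = ...)`), which is the supported path rather than a
different heuristic.

**Tolerance radii.** 1.5 Å for all feature kinds and 1.2 Å excluded-volume
spheres. These sit near the defaults of widely used pharmacophore software;
they are stored in the model JSON, so a model file is self-describing and
the radii are data, not code. Feature directionality (lone-pair or ring
normal) is perceived and carried on the feature points but deliberately
*ignored in matching*: matching is distance-only against spheres, because
angle tolerances add parameters that are hard to justify without
system-specific calibration.

## Feature perception

Perception uses an explicit, versioned rule table rather than a proprietary
rule base, and is defined entirely on heavy atoms so un-protonated
structures work:

* **HBA**: N or O with a free lone pair. Excluded: positively charged N,
  amide N, aniline N, pyrrole-type aromatic N, and aromatic O/S ring
  members. Included: carbonyl, sulfonyl/sulfonamide, ether and hydroxyl O,
  pyridine-type ring N.
* **HBD**: N or O bearing at least one hydrogen, explicit or implicit by
  standard valence (implicit counts are exact on Kekulé input).
* **ARO**: centroid and unit normal of each aromatic ring. A ring is
  aromatic when each member either carries a double/aromatic bond inside the
  ring or is an N/O/S lone-pair donor; a geometric fallback (planar ring,
  bond lengths 1.30-1.46 Å) covers order-less input such as PDB-extracted
  ligands.
* **HYD**: aromatic ring centroids (so hydrophobic model spheres can sit on
  rings), centroids of maximal connected sets of ≥ 2 non-ring apolar heavy
  atoms (C/S/halogen with no bonded N/O), and each halogen bonded to carbon.
  Halogens count because van der Waals contacts of ring chlorines are a
  recurring recognition element in hydrolase pockets.

The ring-centroid duplication (ARO and HYD at the same point) is collapsed
during matching so a ring can satisfy at most one model sphere.

## Matching

**In-place** (`match_pose()`): poses are matched exactly where they are -
docking coordinates are never touched. The maximum-cardinality one-to-one
assignment of ligand points to kind-compatible spheres is found by
depth-first search; with the ≤ 8 features of a receptor-based model this is
exact and fast, and the test suite checks it against exhaustive enumeration.
Cardinality ties break by minimal summed center distance, then feature-id
order, so results are deterministic.

**Alignment mode** (`match_conformers()`): for library screening, each
conformer is free to move. Candidate correspondences between mandatory
features and kind-compatible ligand points are enumerated with
pairwise-distance pruning (|d_model − d_ligand| ≤ r_i + r_j), each survivor
is realized by least-squares rigid superposition (Kabsch), extended greedily
to optional features (nearest unused compatible point within tolerance), and
tested against the excluded volumes; clashing placements are discarded. The
greedy optional extension is a deliberate trade: it is bounded-cost, and the
brute-force oracle in the tests quantifies the (empirically zero, on planted
fixtures) gap on small instances. Enumeration is capped at 10^5
correspondences; hitting the cap warns and returns the best result so far.
Conformer generation itself is out of scope - any generator can supply
conformers via multi-record SDF.

## Interaction geometry

Defaults, all configurable through `interaction_criteria()`:

| criterion | default | note |
|---|---|---|
| H-bond heavy-atom distance | ≤ 3.5 Å | donor/acceptor roles must be chemically possible |
| donor angle (only with explicit H) | ≥ 120° | heavy-atom-only inputs skip it |
| hydrophobic contact | ≤ 4.5 Å | apolar = C/S/halogen with no bonded N/O |
| π-stack centroid distance | ≤ 4.5 Å | ligand ring × Phe/Tyr/Trp/His ring |
| π-stack interplanar angle | ≤ 30° | face-to-face only |

Water-mediated H-bonds are handled by a dedicated water-bridge detector:
ligand polar atom within H-bond distance of the water oxygen *and* the water
within H-bond distance of at least one listed partner residue. Requiring
one arm (not both) reflects that the two partner arms of a structural-water
network rarely hold simultaneously in every frame. Waters are therefore not
listed as direct H-bond partners by `detect_interactions()`.

The pose filter (`filter_pose()`) passes a pose when every required residue
receives a direct H-bond, the structural-water bridge holds, and at least
2 of the model's 4 hydrophobic features are occupied *in place* - the
hydrophobic criterion is a sphere match, not raw contact counting, so the
filter and the pharmacophore express the same geometry.

## Pose consensus

`pose_rmsd()` is in-place heavy-atom RMSD (docking convention: no
superposition), symmetry-corrected by default via the molecule's
element- and bond-order-colored graph automorphisms (VF2, capped at 10^4),
so topologically equivalent atoms - a flipped para-substituted ring - do not
inflate the value. Self-docking validation thresholds at 2.0 Å *strictly*;
boundary values fail, matching the convention "below 2.0 Å".

Consensus clustering is agglomerative complete linkage, implemented in the
package (it is part of the method, with `stats::hclust` serving as the
independent oracle in the tests): merge the two clusters with the smallest
maximum member-pair distance until that distance reaches the threshold.
Equal merge distances resolve by the lexicographically smallest label pair,
making partitions label-order invariant. *Full consensus* - every
reciprocal RMSD strictly below 2.0 Å - is definitionally equivalent to a
single complete-linkage cluster at that threshold, and the suite
property-tests the equivalence on random matrices.

## MD trajectory filter

Trajectories arrive as multi-model PDB (a deliberate, documented limitation:
no binary DCD/XTC, which keeps the package dependency-light; typical
post-processing pipelines can emit PDB frames). Ligand RMSD is computed
per frame against frame 1 after least-squares superposition of protein
α-carbons - a near no-op for trajectories run with restrained α-carbons,
protection for unrestrained ones. Occupancy is the fraction of frames (all
supplied frames; no striding assumptions) in which an interaction satisfies
the same geometric criteria used for static poses.

The acceptance filter is strict on both bounds: mean ligand RMSD < 2.0 Å
and required occupancies > 0.70 ("more than 70%" excludes exactly 70%). The
canonical requirement set is: the arginine anchor, the structural-water
bridge, and at least one of the two oxyanion-hole amides. Mean (not median)
is used as the "average RMSD". Structural-water tracking defaults to
identity (follow the same water); a nearest mode exists for engines that
exchange waters.

## The synthetic-fixture generator

Fixtures are geometric, not energetic: no force field is involved, and the
generator's job is to plant ground truth that the analysis operations must
recover exactly.

* `make_reference_complex()` - a fixed 11-residue pocket + 24-atom ligand
  realizing the full recognition motif (three direct H-bonds, one water
  bridge, four packed hydrophobic sites, one π-stack) with ≥ 0.3 Å margins
  on every criterion, so no planted interaction is boundary-flaky.
* `make_library()` - fragment "stars" (C=O for acceptors, C-C pairs for
  hydrophobics) placed on a chosen feature subset, jittered well inside the
  tolerance radii, then moved to a random rigid frame. The planted match
  size is recovered by alignment-mode matching by construction.
* `make_pose_ensemble()` - realizes a target pairwise-RMSD matrix by pure
  translations (classical MDS embedding plus stress polishing): the
  in-place RMSD of two translated copies *equals* the translation distance,
  which makes the construction exactly verifiable, unlike composed random
  rigid moves.
* `make_trajectory()` - per frame, partner atoms are re-placed at the native
  H-bond distance (present) or 0.3 Å beyond the cutoff (absent), on top of
  the jittered ligand, so planted occupancies are recovered exactly;
  isotropic Gaussian jitter (E[RMSD²] = 3σ²) and an optional constant drift
  control the RMSD statistics.

What fixtures do **not** emulate: conformational strain, realistic packing
densities, protonation equilibria, correlated frame-to-frame dynamics, or
decoys that are *almost* hits. Passing tests therefore demonstrate
correctness of the geometry and logic, not screening enrichment on real
libraries.

## Problem sizes and determinism

The shipped test and acceptance runs use sizes chosen to exercise every code
path while staying desk-scale: libraries of 20-100 planted molecules,
pose ensembles over 3-6 mock methods, trajectories of 15-200 frames, and
100-200 random matrices for the clustering oracle. Every stochastic fixture
takes an explicit seed and is bit-stable under it; the pipeline report
serializes to byte-identical JSON on reruns.

## Other design notes

* The novelty check uses ChemmineR atom-pair descriptors with Tanimoto
  similarity scaled to 0-100, an open stand-in for proprietary 2D similarity
  engines; the conventional novelty bound of 80 is a configurable default,
  not a constant.
* SMILES and MOL2 input pass through OpenBabel and thus arrive Kekulized;
  aromaticity is re-perceived by the package's own rules.
* PDB alternate locations keep 'A'/blank only; occupancy and B-factors are
  read and ignored. Bonds of PDB-extracted ligands are inferred from
  covalent radii (1.25 × radius sum) and carry single orders - the geometric
  aromaticity fallback compensates.
* If no full mandatory correspondence is geometrically feasible in alignment
  mode, the result reports zero matches with `mandatory_satisfied = FALSE`
  rather than searching partial mandatory subsets; screening treats such
  molecules as non-hits either way.
* When several docking poses are supplied per compound and method, the first
  record is taken as the method's top-ranked solution - record order is
  rank order, the convention of every docking format this package reads.

## Known limitations

Charged/ionic features and halogen-bond typing are not modeled (the feature
vocabulary covers HBA/HBD/HYD/ARO); directionality is not enforced in
matching; trajectory input is text PDB only; protonation states are taken
as given. These are explicit boundaries, not accidents: each would add
parameters that cannot be validated within a geometric fixture framework.
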