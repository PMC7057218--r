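---
title: "Characteristic-vector networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characteristic-vector networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvnet)
```

## The characteristic-vector model

For any peptide window of at least three residues, the characteristic
vector (CV) runs from the centroid of the window's C-alpha atoms to the
centroid of its carbonyl O atoms. Because carbonyl orientation is the
lever of the hydrogen-bonding torsions, the CV condenses the local
main-chain conformation into a single vector: over sliding tripeptide
windows, CV moduli concentrate near 2.2 Å in alpha-helices and 1.4 Å in
beta-strands, and the angle between consecutive CVs falls in roughly
5–10° for helices versus 45–57° for strands. The formalism needs no
hydrogen-bond inference, which makes it robust to the distorted geometry
of low-resolution models, and it applies unchanged to windows of any
length (longer windows smooth more and are blind to short elements; the
package default is the tripeptide).

All pairwise relations between CVs — the angle between the two vectors
and the Euclidean distance between their midpoints — are kept in a
complete graph. Completeness is what later guarantees that a fold present
in an annotated structure cannot be missed by the fold search: every pair
of fragments is connected by edges carrying their exact relative
geometry.

Two points are open in the definition of the CV–CV distance (which two
points of a vector to measure between). We use the vector midpoints:
midpoints are symmetric in the two endpoints, move with the fragment, and
make the 6 Å sheet criterion geometrically meaningful. `build_cv_graph()`
accepts `distance_at = "origin"` as the alternative.

## Annotation: penalty scores and strictness

Each CV is scored against an ideal helix and an ideal strand with a
penalty built from three descriptors:

| descriptor | helix ideal | strand ideal | scale | weight |
|---|---|---|---|---|
| CV modulus (Å) | 2.2 | 1.4 | 0.8 | 0.50 |
| mean angle to sequence-neighbour CVs (°) | 7.5 | 52.5 | 45 | 0.35 |
| CA(i)–CA(i+2) span (Å) | 5.5 | 6.6 | 1.1 | 0.15 |

Each term contributes `w * min(1, |observed - ideal| / scale)`, so both
scores live in [0, 1]. The scales are set so that each canonical geometry
saturates the penalty of the opposite hypothesis: an ideal helix scores
essentially 0 against the helix ideals and 1 against the strand ideals,
which makes the full [0, 1] strictness range usable. The third descriptor
is the two-step C-alpha span rather than the consecutive CA–CA distance:
consecutive spacing is ~3.8 Å in *every* regular conformation and cannot
discriminate, whereas the i→i+2 span separates the tight helical turn
(~5.5 Å) from the extended strand (~6.6 Å). The strand angle ideal of
52.5° sits mid-band; note that geometrically exact strands built from the
canonical antiparallel torsions (φ = −139°, ψ = +135°) give consecutive
CV angles of ~57°, while strands in real structures — flatter, pleated,
and mixed with parallel-sheet conformations — fall between ~45° and 55°.
The scoring scales absorb this spread.

A CV's label is the hypothesis with the lower score, **provided** the
absolute score difference exceeds the *strictness* threshold of that
hypothesis; otherwise the CV is coil. Strictness is the single most
important user parameter: low values extend elements and tolerate bent or
distorted geometry, high values annotate only short, near-ideal
fragments. Helices and strands take separate thresholds (defaults 0.5 and
0.3, the values of the package's reference library run). Scoring is
refined over a few iterations in which the argmin labels of the two
sequence-neighbour CVs grant a ±10% score bonus/penalty, sharpening the
reading of the structural environment; iteration stops at a label fixed
point (cap 10). The refinement is deliberately independent of the
strictness threshold, which is applied once at the end: this yields the
monotonicity property that the non-coil residue set at a higher
strictness is always a subset of the set at a lower one — the behaviour
the strictness dial promises — and it makes the per-residue "maximum
strictness" map (written into the B-factor column of `strictnesses.pdb`,
scaled to 0–100) exact rather than approximate.

Residue labels follow three rules applied in order: (i) a residue whose
member CVs all agree takes their label; (ii) a residue with two helix CVs,
no strand CV and a helix successor is extended into the helix (evaluated
from the C-terminus so extensions propagate); (iii) a coil residue with
two strand CVs and no helix CV becomes strand, as does one with at least
one strand CV, no helix CV and a coil residue within two positions. We
additionally require "no helix CV" in the second clause of rule (iii),
which prevents helix/strand junction residues from being pulled into
strands. Runs shorter than three residues are relabelled coil: three
residues is the minimum window that defines a CV, so shorter "fragments"
have no geometric support.

### Sheets and the fragment graph

Two strands join a sheet when at least 40% of their inter-fragment CV
angles fall in the parallel band **or** in the antiparallel band, and
their minimum CV–CV distance is below 6 Å; sheets are the transitive
closure of this pairing. The default bands are [0°, 40°] and [120°, 180°].
Tripeptide CVs tilt about 30° off the strand axis with alternating pleat
phase, so CV pairs across exactly antiparallel strands concentrate
between ~120° and 180° (and across parallel strands between 0° and ~57°);
bands narrower than this — e.g. [150°, 180°] — miss geometrically perfect
antiparallel pairs whose pleat phases are opposed. Both bands, the 40%
fraction and the 6 Å bound are configurable. The minimum (not mean)
inter-fragment distance is used because it is robust to length-mismatched
strand pairs.

Fragments become supernodes of a fragment graph whose edges carry the
minimum, maximum and mean of all inter-fragment CV angles and distances.
Edge weight is the inverse mean distance, doubled when the two fragments
share a type (`same_type_factor = 2`), so spatial proximity dominates and
sheet packing is promoted.

## Decomposition

Community clustering on the fragment graph maximizes weighted Newman
modularity — the fraction of edge weight inside groups minus its random
expectation. The package exposes the eight standard igraph algorithms
(fastgreedy by default, the first of the menu); stochastic ones take an
explicit seed (default 42). Modularity is always recomputed directly from
the weight matrix, independently of the backend, and an exhaustive
partition search (`best_partition_exhaustive()`) serves as an oracle on
small graphs.

Two constraints are absolute, not best-effort. `sheets_together`
collapses each sheet into a single pre-merged node before clustering, so
no sheet can be split. `homogeneous_size` re-clusters up to 20 rounds,
each time downweighting the internal edges of the largest group by 0.8,
until group sizes differ by at most one fragment; the bias mechanism is
the edge weights themselves, which is the lever the clustering actually
optimizes. Hierarchical mode cuts the agglomerative merge tree at every
granularity from one single cluster to one fragment per group, reporting
recomputed modularity per level. The grouped PDB assigns one chain
identifier per group; coil residues, which belong to no fragment, go to
the group of the nearest fragment by minimum C-alpha distance so that the
output model is exhaustive and directly usable for rigid-group
refinement.

## Fold matrices and the recursive search

A structure's fold matrix is the square matrix over all its CVs in chain
order: the first diagonal stores each CV's modulus and label, the second
diagonal the relation between contiguous CVs (identifying
secondary-structure elements in linear time), and the remaining cells the
(angle, distance) relations that characterize the fold. A template's
fragments are compared block-wise against candidate windows in the
target: a candidate for an m-CV template fragment is any run of m
consecutive CVs of one target stretch whose majority carries the
fragment's label. Allowing the window to extend past annotated fragment
boundaries (into coil-labelled CVs) makes the search robust to fragments
that the strictness threshold shrank or split in distorted models — the
geometry is still in the matrix, and the similarity thresholds do the
actual discrimination.

Block similarity is the percentage of compared cells that agree within
tolerance bands (±15° in angle, ±2 Å in distance, ±0.5 Å in modulus for
the diagonal cells of intra-fragment blocks; all doubled when a cell
involves a coil-labelled CV, so coil relations weigh less strictly). The
bands were fixed so that a template compared against itself scores
exactly 100% and perturbation sweeps degrade smoothly. Two thresholds
control the search: the secondary-structure score (intra-fragment blocks,
default 45%) and the tertiary-structure score (inter-fragment blocks,
default 55%) — lax local geometry, stricter fold arrangement, the
reference parameterization for Rossmann-type extractions. The intra
threshold is applied per fragment when proposing candidates; the inter
threshold applies to the aggregate over all fragment pairs (cells pooled,
not averaged per pair), which is the less brittle reading of a
percentage threshold for folds whose pairs have very different sizes.

The search is a depth-first forest over fragment assignments. Branches
are pruned with an *admissible* bound: a partial assignment is abandoned
only when even a perfect completion (all remaining inter-fragment cells
matching) could not reach the tertiary threshold. This preserves
completeness — the search provably returns exactly the set a brute-force
enumeration over all candidate combinations accepts, which the test suite
verifies on 100 randomized targets of up to six fragments. Assigned
windows must not share target residues; template fragment order in the
target is optional (`require_connectivity`). By default only one
representative of equivalent monomers (chains with identical residue
sequences) is searched; `multi_chain = TRUE` searches all chains and
admits folds spanning several of them, e.g. coiled coils.

Matches can be filtered by a position-wise sequence pattern (`X` = any
residue), by the presence of a disulfide bridge (an S-gamma pair within
1.8–2.5 Å, standard bond geometry) and by a maximum C-alpha r.m.s.d. to
the template after optimal superposition (5.0 Å default). Surviving
matches are superposed onto the template, stamped with a common B factor
(25.0 Ų default) and written as `pdbid_x_yyyy.pdb` — source identifier,
model index (0 except for multi-model entries) and a four-digit counter.
Library clustering offers exhaustive pairwise-r.m.s.d. complete linkage
(deterministic, the finest criterion), binning by r.m.s.d. to the
template, and seeded random subsetting for very large libraries.

## Superposition

Superposing a small, possibly discontinuous fold onto a complete
structure reuses the fold search for correspondences, so disconnected
fragments and repeated sites are handled naturally. Each candidate site
is refined by iterative inverse-variance weighting: superpose, weight
every atom pair by `1 / (deviation² + ε)` with ε = 1e-4 Ų (normalized to
mean 1), re-superpose, until the r.m.s.d. changes by less than 1e-6 Å or
20 iterations. The optimal rigid transform is computed by SVD of the
weighted covariance with the determinant sign corrected, so a proper
rotation is always returned (mirror images are never "matched"). Site
finding works on C-alpha atoms; the final refinement uses all four
main-chain atoms by default (configurable to C-alpha only).

For every fragment of the core longer than five residues, up to three
residues may be trimmed from each extremity (never below five remaining
residues); all trim combinations are enumerated, each refined, and the
lowest r.m.s.d. wins, with ties resolved toward fewer trimmed residues.
If the combination count exceeds 1e5 the search falls back to greedy
per-fragment trimming. Since trimming a core can only lower the r.m.s.d.
over the remaining atoms, the reported value must be read together with
the core size. Overlapping sites (sharing any target residue) are reduced
to the lower-r.m.s.d. one (ties: earlier residue range); surviving sites
are reported separately in chain order. The reported transform maps the
*target* onto the template frame — its inverse places the fold at the
site — and the superposed target coordinates are written per site.

## The synthetic generator

All tests run against structures built in torsion space by sequential
atom placement, so every phi/psi is exact by construction: helices at
(−57°, −47°), strands at (−139°, +135°) with an alternating ±5° psi pleat
(canonical Pauling values; ideal bond geometry), coil from a fixed
irregular torsion cycle far from both regular basins. Elements are
canonicalized (axis along x, pleat plane oriented) so placement
transforms compose predictably: `sheet_elements("UDU")` stacks strands
4.8 Å apart with "D" strands rotated 180° about the sheet normal.
Composite fixtures can also be joined into one chain through coil
linkers. Every fixture ships its ground truth — per-residue labels,
element table, sheet membership (from construction geometry), group
membership — and all recovery tests are phrased against that truth.

Two perturbations emulate imperfect models. Coordinate noise is a smooth
low-frequency displacement field (two random harmonics, 20–40 residue
wavelengths, rescaled to the requested per-atom sigma, plus a small
independent jitter, with a deterministic repair of any peptide bond the
tail of the draw pushes out of range): real imperfect models deform
smoothly under restrained refinement and never break peptide-bond
geometry, which independent per-atom noise would do at useful amplitudes.
Carbonyl misorientation rotates selected C=O bonds about the C–CA axis,
reproducing the signature of distorted helices whose carbonyls stray from
the helical axis: shorter CV moduli, larger consecutive-CV angles, and a
visible dip in the per-residue strictness map.

What the generator does *not* emulate: side chains (beyond S-gamma
stubs for disulfide tests), sequence-dependent backbone preferences, the
conformational diversity of real loops, solvent and crystal contacts.
Tests passing on fixtures therefore demonstrate the correctness of the
geometry, the search and the bookkeeping under controlled conditions; on
real structures the annotation percentages depend on the strictness
calibration, and a geometry-only method will always read some extended
loops as strand-like where hydrogen-bond-based tools do not. The test
suite includes a comparison of annotation percentages at three strictness
values against the published figures for PDB entry 1xoc; it runs whenever
that entry is present at `inst/extdata/1xoc.pdb` (the coordinates are not
redistributed with the package).

## Numerical choices and limitations

Degenerate (zero-modulus) CVs are kept in the graph but excluded from
angle-based scoring and take maximal penalties on both hypotheses. CVs
without sequence neighbours (single-CV stretches) drop the angle
descriptor and renormalize the remaining weights. The C–N connectivity
test accepts 1.1–1.8 Å, wide enough for distorted low-resolution peptide
bonds; altloc ties break to the lowest letter; insertion codes order
after their base number. Problem sizes in the checks are deliberately
small — fixtures of 2–6 elements, 100 randomized search targets,
libraries of 10 models — chosen so every oracle (exhaustive partition
search, brute-force fold enumeration, full trim enumeration) remains
exactly computable.

Known limitations: the annotation is geometric and will disagree with
hydrogen-bond-based annotation on marginal, bent or PPII-like regions;
the homogeneity constraint is a declared edge-weight rescaling heuristic,
not a guaranteed-optimal balanced partition; the fold search compares
fragments window-wise and does not model insertions *within* a single
secondary-structure element; and symmetry mates are not generated, so
folds completed by crystallographic symmetry are out of reach.
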