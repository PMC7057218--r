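# cvnet

Characteristic-vector networks for protein main-chain geometry.

`cvnet` is an R toolkit for crystallographers and structural
bioinformaticians who work with *small, possibly discontinuous* protein
fragments — the search models of fragment-based molecular replacement.
It describes the main chain through **characteristic vectors** (CVs): for
every sliding window of three residues, the vector from the centroid of
the C-alpha atoms to the centroid of the carbonyl O atoms,

```
CV(i) = centroid(O_i, O_i+1, O_i+2) − centroid(CAi, CAi+1, CAi+2).
```

CV moduli concentrate near **2.2 Å in alpha-helices** and **1.4 Å in
beta-strands**; consecutive-CV angles near **5–10°** (helix) versus
**~45–57°** (strand). All pairwise CV relations (angle, midpoint
distance) form a complete graph, and everything else is built on that
network — no hydrogen-bond inference anywhere, which keeps the method
usable on distorted, low-resolution models:

1. **Annotation** — each CV is scored against helix and strand ideals
   with a penalty in [0, 1]; it is labelled by the lower score only if the
   score difference exceeds a tunable **strictness**, otherwise coil.
   Low strictness extends bent elements, high strictness keeps only
   near-ideal fragments, and the non-coil set shrinks monotonically as
   strictness rises. Per-residue confidence goes into `strictnesses.pdb`.
2. **Decomposition** — fragments become supernodes of a graph weighted by
   inverse mean CV distance; community clustering maximizes modularity
   `Q = Σ_ij (A_ij − k_i k_j / 2m) δ(c_i, c_j) / 2m` to cut a fold into
   compact rigid groups (one chain ID per group, ready for rigid-group
   refinement), with optional sheet-preserving and size-homogeneity
   constraints and a hierarchical mode.
3. **Fold libraries** — a fold is a CV-indexed matrix (moduli/labels on
   the diagonal, consecutive relations on the second diagonal,
   inter-fragment angles/distances elsewhere). A recursive, provably
   complete search extracts every geometric occurrence of a template fold
   from a set of structures — sequence-free, tolerant of reordered or
   inserted fragments — filters them (sequence pattern, disulfide,
   max r.m.s.d.), superposes them on the template and writes a library of
   `pdbid_x_yyyy.pdb` models with a common B factor.
4. **Superposition** — small discontinuous folds are located via the fold
   search, then fitted by weighted Kabsch superposition with iterative
   inverse-variance weighting and exhaustive extremity trimming (up to 3
   residues per end of fragments longer than 5); every non-overlapping
   site is reported separately.

A synthetic-structure generator (`build_ideal_element()`,
`assemble_fold()`, `perturb()`) builds helices, strands, sheets and
composite folds from canonical torsions with exact ground truth, so the
whole pipeline is testable without any database.

## Worked example

```r
library(cvnet)

## a composite local fold: two antiparallel strands packed against a helix
fold <- assemble_fold(c(sheet_elements("UD", length = 7, spacing = 4.8),
                        list(element("ah", 9, t = c(0, 2.4, 9)))))
ann <- annotate_structure(fold$structure, strictness_ah = 0.5, strictness_bs = 0.3)
ann
#> <cv_annotation> 17 CVs, 3 fragments; 39% helix, 61% strand

round(tapply(ann$cvs$modulus, ann$cvs$stretch, mean), 2)
#>    1    2    3
#> 1.43 1.43 2.26

ann$sheets
#> [1]  1  1 NA

dec <- decompose_fold(ann)
dec
#> <cv_decomposition> 2 groups over 3 fragments (fastgreedy), Q = -0.091

## search the fold against a noise-perturbed copy and extract the match
td <- tempfile(); dir.create(file.path(td, "db"), recursive = TRUE)
write_structure(fold$structure, file.path(td, "template.pdb"))
write_structure(perturb(fold$structure, noise_sigma = 0.3, seed = 7),
                file.path(td, "db", "copy1.pdb"))
manifest <- generate_library(file.path(td, "template.pdb"), file.path(td, "db"),
                             out_dir = td, multi_chain = TRUE)
manifest[, c("file", "ss_score", "tt_score", "rmsd_to_template")]
#>               file ss_score tt_score rmsd_to_template
#> 1 copy1_0_0001.pdb      100      100        0.4179273
```

Reading the numbers: the two strand stretches carry CVs of mean modulus
1.43 Å and the helix 2.26 Å — the canonical strand/helix values. The two
strands are detected as one sheet (`1 1`, helix `NA`). The fastgreedy
decomposition groups the sheet against the helix; modularity is low
because a single compact fold is, by construction, *not* decomposable
into well-separated communities. The library search finds the fold in the
σ = 0.3 Å perturbed copy with 100% secondary- and tertiary-structure
similarity and places the extracted model 0.42 Å from the template —
below the noise amplitude, because superposition averages it out.

A command-line front end covering the four tasks plus fixture generation
is installed as `exec/cvnet` (run e.g.
`Rscript "$(Rscript -e 'cat(system.file("exec","cvnet",package="cvnet"))')" annotate --input model.pdb --out run/`);
every run writes a machine-readable `summary.json` manifest.

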