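Package: cvnet
Title: Characteristic-Vector Networks for Protein Backbone Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents protein main-chain geometry as networks of
    characteristic vectors (CVs), the vectors joining the centroid of the
    C-alpha atoms of a peptide window to the centroid of its carbonyl O
    atoms. On top of this representation the package performs four tasks:
    flexible, hydrogen-bond-free secondary-structure annotation under a
    tunable strictness; decomposition of a fold into compact rigid groups
    by community clustering of the fragment graph; sequence-free
    extraction of all geometric occurrences of a template fold from a set
    of structures and generation of superposed fragment libraries for
    molecular replacement; and superposition of small, possibly
    discontinuous fragments onto complete structures with iterative
    inverse-variance weighting and extremity trimming. A synthetic
    structure generator builds ideal helices, strands, sheets and
    composite folds from canonical backbone torsions with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
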