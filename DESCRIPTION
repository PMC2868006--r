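Package: triadKDE
Title: Sequence-Only Protein-Protein Interaction Prediction with Triad
    Significance Features and Variable-Bandwidth Kernel Density Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions from primary sequence
    alone.  Each protein is reduced to seven physicochemical amino-acid
    groups and encoded by the permutation significance of its conjoint
    triads: the probability that a composition-preserving shuffle of the
    sequence shows fewer occurrences of each grouped three-residue window
    than actually observed.  Pairs of proteins are classified with a
    relaxed variable kernel density estimator (RVKDE) whose per-sample
    Gaussian bandwidths derive from k-nearest-neighbour radii.  Includes
    construction of class-imbalanced benchmark datasets at controlled
    positive-to-negative ratios with disjoint negative sets, the trivial
    baseline predictors and precision-sensitivity evaluation used to study
    imbalance, and a synthetic proteome/interactome generator with
    plantable triad-level signal for end-to-end testing without external
    interaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
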