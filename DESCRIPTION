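Package: intronscape
Title: Fitness Landscape Analysis of a Dynamic Group I Intron RNA Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse combinatorially complete deep mutational
    scanning experiments on the P1ex/P10 region of the Tetrahymena group I
    intron, and to simulate such experiments. Covers enumeration and
    combinatorics of the 4^8 genotype space, nearest-neighbor free energies
    of the forced P1ex and P10 helices, count-to-fitness estimation from
    pre-/post-selection amplicon counts across replicates, diversity and
    distribution-of-fitness-effects summaries, pairwise and higher-order
    epistasis (including a helix mirror test), and gradient-boosted-tree
    feature attribution with exact SHAP values. A two-state synthetic
    landscape generator emulates the selection experiment so that every
    stage of the pipeline can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    mclust,
    xgboost,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2
Config/testthat/edition: 3
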