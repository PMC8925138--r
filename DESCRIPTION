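Package: msageom
Title: Inter-Residue Geometry Prediction from Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binned inter-residue geometries (Cbeta-Cbeta distance and
    the omega/theta dihedrals and phi planar angle) for a protein from its
    multiple sequence alignment. Per-position features and row-attention maps
    supplied by a protein-language-model embedder are combined into a pairwise
    feature map and passed through a dilated residual convolutional network
    with four classification heads, one per geometry. The package provides A3M
    alignment parsing, diversity-based MSA subsampling, ground-truth geometry
    featurization from backbone coordinates, network training with gradient
    accumulation, CASP-style long-range contact evaluation, and restraint-file
    output for a downstream structure-realization engine. A deterministic stub
    embedder and synthetic MSA/backbone generators make the full pipeline
    testable without external models or databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
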