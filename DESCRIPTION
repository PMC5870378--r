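Package: TRFLPtools
Title: Terminal Restriction Fragment Length Polymorphism Community Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of terminal restriction fragment length
    polymorphism (T-RFLP) community fingerprints. Predicts terminal
    fragment sizes and ARDRA fingerprints from 16S rRNA gene sequences by
    in-silico PCR with degenerate primers and in-silico restriction
    digestion. Ingests, size-filters, bins and replicate-merges
    electropherogram peak tables into relative-abundance community
    matrices. Computes diversity indices (richness, Shannon, evenness,
    Simpson) and core/shared/unique ribotype classifications, Bray-Curtis
    dissimilarities, nonmetric multidimensional scaling by multi-start
    isotonic-regression minimisation of Kruskal stress, ANOSIM permutation
    tests and UPGMA clustering. Includes a parameterised synthetic
    community generator with known ground truth for validating every
    pipeline stage.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
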