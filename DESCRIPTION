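Package: cottonDGE
Title: Tag-Based Digital Gene Expression Profiling of a Leaf Senescence
    Time Course
Version: 0.1.0
Authors@R: person("DGE", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for NlaIII digital gene expression
    (DGE) tag profiling against a dual-genome (allopolyploid) reference:
    virtual CATG+17-nt tag-library construction from two merged diploid
    genomes with cross-genome redundancy removal, one-mismatch tag mapping
    with ambiguity filtering, tags-per-million normalization, pairwise
    Audic-Claverie exact-count differential expression with
    Benjamini-Hochberg FDR and fold-change filters, time-course K-means and
    hierarchical clustering with trajectory-type classification,
    annotation-set over-representation testing, and qPCR cross-validation
    by the comparative 2^-ddCt method.  A ground-truthed synthetic-data
    generator emulating a six-time-point senescence study design makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
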