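Package: foldclosure
Title: Transitive-Closure Structural Similarity Search in Protein Fold Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exhaustive structural-similarity search over a large protein
    structure database by iterative transitive closure on a precomputed
    fast-comparison neighbor graph. Candidate shells drawn from a noisy,
    incomplete e-value graph are validated against the original query by a
    precise aligner score (Dali-style Z-score and alignment length), with
    greedy representative selection and redundancy masking to keep the
    number of expensive validations practical, and a final validation round
    for deferred redundant neighbors. Includes a synthetic hierarchical
    fold-space generator for end-to-end testing without external tools,
    query-anchored stacked alignments with FASTA export and row seriation,
    metadata crosslinking and family assignment, and an evaluation framework
    (suffix-filtered reference sets, precision/recall/F1, Fmax, precision-
    recall curves and AUPRC, hierarchical pair stratification).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
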