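Package: paraldiv
Title: Conservation-Pattern Divergence Analysis of Paralogous Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies columns of a grouped protein multiple sequence
    alignment by Shannon-entropy conservation within paralog groups,
    assigns type I / type II / mixed functional-divergence calls, and
    summarises the resulting conservation patterns with exact
    combinatorial and Poisson statistics (set-partition enumeration of
    possible patterns, Bonferroni-style Poisson significance thresholds,
    expected pattern frequencies under an independence model). Includes
    alignment-to-structure residue mapping with distance-cutoff
    extraction of binding-pocket and dimer-interface residue sets, and a
    synthetic-alignment generator with planted, known-truth column
    classifications for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
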