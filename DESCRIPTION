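Package: groELprofiler
Title: Species-Level Bifidobacterium Profiling with Degenerate groEL Primers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for species-level profiling of Bifidobacterium communities
    with a degenerate primer pair targeting a hypervariable region of the
    single-copy groEL (cpn60) chaperonin gene. Provides IUPAC degenerate-primer
    matching and in-silico PCR against reference sequences, marker resolving-power
    analysis (pairwise percent-identity matrices, cross-marker comparison,
    neighbor-joining distance trees), a paired-end amplicon processing pipeline
    (read merging, quality/primer filtering, greedy OTU clustering, best-hit
    taxonomic classification, abundance profiling), and a seeded mock-community
    simulator with dilution series for sensitivity (limit-of-detection) studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
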