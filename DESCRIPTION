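Package: viromerge
Title: Viral Contig Curation, Segment Association and Abundance Dynamics
    for Fermentation Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly toolkit for RNA virome discovery in fermentation
    metatranscriptomes. Curates assembled contigs (length filtering, greedy
    redundancy clustering, terminal-overlap merging under a bounded-mismatch
    end-alignment rule, chimera detection), assigns known/novel taxonomic
    status against a reference virome, discovers open reading frames under
    alternate genetic codes, associates multi-segmented narnavirus segments
    with custom profile hidden Markov models and exact terminal pairing,
    detects 3'-terminal stem-loops, and tracks abundance (TPM) and alpha
    diversity across fermentation time points. Ships a seeded synthetic-data
    generator that plants every structure the pipeline detects, so the whole
    workflow is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
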