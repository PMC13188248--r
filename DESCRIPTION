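Package: r2scout
Title: Curation and Classification of R2-Like Retrotransposons in Ribosomal DNA Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery, curation and classification of R2-like non-LTR
    retrotransposons that insert site-specifically into 28S ribosomal RNA
    genes. Provides a synthetic-data generator for rDNA arrays with embedded
    elements and simulated reads, seeded affine-gap local alignment for
    element discovery, 28S target-site junction analysis with nick-site
    offsets, a zinc-finger/Myb/reverse-transcriptase domain-architecture
    grammar, position-specific scoring matrix (PSSM) lineage placement,
    neighbor-joining phylogenetics with bootstrap support, and discrete-gamma
    per-site evolutionary rate estimation, plus an end-to-end pipeline with
    summary reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
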