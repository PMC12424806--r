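Package: unitigr
Title: Desk-Scale Unitig/Contig Assembly and K-Mer Search Across Accessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact de Bruijn graph assembler and k-mer search engine for
    desk-scale sequencing experiments. Builds unitigs (maximal non-branching
    paths over solid canonical 31-mers) and contigs (unitigs after tip
    clipping, bubble popping and weak-link removal), annotates sequences with
    an 8-bit quantized mean abundance with bounded relative error, detects
    circular contigs and trims their terminal repeats, and writes
    BCALM2-style FASTA link headers and GFA1 graphs. A per-accession Bloom
    filter index with Findere-style composed queries answers
    coverage-fraction searches (which accessions contain a given fraction of
    a query's k-mers) and exact matching-sequence extraction. Includes seeded
    generators for genomes and error-bearing reads so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
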