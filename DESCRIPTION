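Package: seedex
Title: Seed-and-Extend Nucleotide Similarity Search with a Read-Only Q-Gram Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: CPU implementation of a seed-and-extend nucleotide similarity
    search for metagenomic reads against reference genomes. Reference k-mers
    are held in a read-only q-gram index built from sorted key/value arrays
    with an exclusive-prefix-sum gateway, over-represented k-mers are masked
    by a repeat threshold, candidate seeds are thinned by a two-pass
    surrounding-area filter, and surviving representative seeds are extended
    by banded affine-gap dynamic programming in glocal (full-query) or local
    mode. Hits carry identity, score, Karlin-Altschul E-value and bit score
    and are written in 12-column BLAST tabular format. Includes a synthetic
    metagenome generator and an evaluation harness for genus-level
    taxonomic-assignment benchmarks (correct-genus-assignment ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
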