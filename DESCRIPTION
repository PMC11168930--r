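Package: palindromekit
Title: Palindrome Discovery and Sequence-Class Annotation for Sex Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects long inverted repeats (palindromes) on chromosome-scale
    DNA sequences by inverted seed-and-extend self-alignment, groups
    homologous palindromes within and across species by transitive closure of
    filtered arm-to-arm alignments, partitions sex chromosomes into
    pseudoautosomal, satellite, ampliconic and ancestral sequence classes,
    applies the standard post-filter to segmental-duplication calls, and calls
    multi-copy and ampliconic gene families from protein sequences.  Ships a
    synthetic chromosome and protein-family generator with planted,
    machine-readable ground truth for end-to-end validation, a small
    statistics kernel (Welch t, Wilcoxon rank-sum, Bonferroni), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
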