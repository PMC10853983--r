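Package: cassandra
Title: Structure-Based Detection and Annotation of Cassandra Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for finding Cassandra terminal-repeat retrotransposons in
    miniature (TRIMs) in genome sequence by their two-LTR structure, annotating
    the 5S rDNA-derived internal promoter (A-Box, intermediate element, C-Box)
    carried mid-LTR, classifying C-Box variants and promoter mimicry, grouping
    elements into families at a 70 percent pairwise-identity threshold and into
    indel-defined variants, comparing LTR sets by windowed dotplots, and
    classifying the 35S-5S rDNA arrangement (linked versus separated) from
    low-coverage reads with a colored k-mer unitig graph. A synthetic-genome
    module generates rDNA arrays, Cassandra and Cassandra-like elements, and
    reads with full ground-truth annotation so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
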