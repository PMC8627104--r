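Package: hicscaf
Title: Iterative Hi-C Scaffolding via Mutual N-Best-Neighbor Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chromosome-scale scaffolds from a draft assembly and Hi-C
    read-pair alignments. Qualified inter-contig read pairs are tallied into a
    contact matrix over contig ends (thirds or halves), normalized by contig
    length, and reduced to a scaffolding graph by mutual N-best-neighbor
    selection and unique-maximum pruning; connected components of the pruned
    graph become scaffold paths. Scaffolding is iterative, with coordinates
    lifted through a GFA-derived plain-text graph format (SAT) between rounds.
    A physical spanning-coverage profile detects and breaks weakly supported
    joins. Includes a seeded Hi-C simulator for validation, AGP/FASTA export,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
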