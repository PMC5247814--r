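Package: rarescan
Title: Degenerate Direct-Repeat Response Element Scanning in Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive enumeration of nuclear-receptor direct-repeat (DR)
    response elements, such as retinoic acid response elements (RAREs), in
    genomic sequences using a degenerate IUPAC motif grammar with variable
    spacers (DR0-DR9). Hits are annotated relative to a multi-gene cluster
    (compartment, nearest downstream gene, distance to the start codon,
    orientation), filtered for cross-species conservation of sequence and
    relative cluster position, and summarised as degenerate IUPAC consensus
    models with per-position information content. A synthetic multi-species
    cluster generator with planted elements and a ground-truth table supports
    end-to-end benchmarking without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
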