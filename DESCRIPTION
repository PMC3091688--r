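Package: globinscan
Title: Annotation and Classification of Teleost Hemoglobin Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates three-exon globin gene models in assembled genomic
    sequence by translated exon search and canonical-splice chaining,
    classifies candidates into putatively functional genes and pseudogenes
    using explicit structural rules, detects non-Bohr beta hemoglobins from
    their protein hallmarks, analyses the tail-to-tail alternating alpha/beta
    cluster layout, types clusters from flanking-gene synteny, and checks
    clade membership with distance-based trees. Ships a synthetic cluster
    generator with exact truth tables so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomeInfoDb,
    BiocGenerics,
    igraph,
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
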