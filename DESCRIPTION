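Package: mitomosaic
Title: Resolving Multipartite Plant Mitochondrial Genomes from Long-Read
    Junction Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to resolve the multipartite structure of plant
    mitochondrial genomes. Starting from assembled organelle contigs plus
    long and short sequencing reads, the package builds a weighted
    scaffold-junction graph from long reads that span 500 bp terminal
    anchors, enumerates the circular subgenomic conformations that the
    graph supports, models the recombination algebra (fusion, fission and
    inverted-repeat flip-flop) relating alternative conformations,
    confirms two-copy repeats by coverage-depth doubling, detects
    plastid-derived insertions (MTPT), and reports standard genome
    statistics. A fully seeded synthetic-genome and read simulator with
    complete ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, Alignment, Assembly, Sequencing, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
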