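Package: kkpminer
Title: Mining Prophage-Encoded Kinase-Kinase-Phosphatase Modules in Annotated Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers kinase-kinase-phosphatase (KKP) gene modules in annotated
    bacterial genomes by a triplet neighboring-gene scan: consecutive same-strand
    gene triplets whose domain architectures read PP2C phosphatase followed by two
    Ser/Thr kinases, one carrying a C-terminal cold shock domain (CSD) and the
    other a forkhead-associated (FHA) domain, filtered by gene length. Assigns
    each cluster a genomic context (prophage, Psu-rescued P4 prophage, mobile
    genetic element linked, or other), groups clusters into families by pairwise
    protein identity, annotates externally built kinase trees with outgroup
    rooting and clade membership, and compares prophage regions by banded global
    affine-gap alignment with an indel-run inventory. Ships a seeded synthetic
    genome generator with planted clusters, typed decoys and a machine-readable
    truth table so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
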