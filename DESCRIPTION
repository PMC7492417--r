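Package: hineminer
Title: Mining Satellite-Like Tandem Repeat Arrays and Helentron-Associated
    Interspersed Elements from Genome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery of short satellite-DNA-like tandem repeat
    arrays (100-500 bp monomers, two or more copies) by k-mer seeded detection
    with wraparound dynamic programming, similarity clustering of arrays with
    cyclic monomer alignment, derivation of left/right flanking consensus
    sequences, annotation of Helentron-associated interspersed element (HINE)
    substructures (subterminal inverted repeats, internal inverted repeat,
    microsatellite, 3' palindrome), assembly and grouping of non-autonomous
    HINE element models including double-array elements, empty-site paralog
    search, and insertion-site preference profiling. A seeded synthetic-genome
    generator plants ground-truth elements, decoys and empty paralogous sites
    so that every stage can be scored against known truth.
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
    GenomicRanges,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Annotation, MobileElements, Repeats
RoxygenNote: 7.3.3
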