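Package: goldenpool
Title: Design of Multi-Kilobase Gene Synthesis from Oligonucleotide Pools
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing Golden Gate assembly of genes from array-synthesized
    oligonucleotide pools. Covers ligation-fidelity scoring of 4-nt overhang sets from
    all-by-all ligation count matrices, genetic-algorithm optimization of high-fidelity
    overhang sets ("hingesets"), protein-preserving sequence domestication (type IIS
    site removal, k-mer uniquification, hairpin avoidance), codon optimization with
    windowed GC-content enforcement and iterative splice-junction purging, constrained
    fragmentation of targets at hingeset junctions, indexed oligo layout under a 250-nt
    budget, orthogonal index-primer and edit-distance-separated barcode design,
    hierarchical two-step assembly planning, an in-silico digest-ligate simulator, and a
    desk-scale barcoded amplicon validation pipeline (read simulation, demultiplexing,
    consensus, clone classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
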