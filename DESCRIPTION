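Package: CaryaPan
Title: Synteny-Constrained Pan-Genomics, Introgression Mapping and F1 QTL
    Analysis for Polyploid-Descended Tree Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative and quantitative genomics of outbred tree
    genomes descended from a whole-genome duplication, modelled on the pecan
    (Carya illinoinensis) multi-genome study design. Implements
    synteny-constrained orthogroup clustering and pan-genome ordering with
    presence-absence variation (PAV) classification, homeolog collinear-block
    counting and rearrangement-rate estimation, Nei-Gojobori Ka/Ks with
    sliding-window quantile landscapes, a local-ancestry hidden Markov model
    with block decoding for introgression detection, and pseudo-testcross F1
    QTL mapping (Kosambi map estimation, LOCO mixed-model LOD scans,
    permutation thresholds, Bayes credible intervals) with
    haplotype-divergence candidate ranking. Includes seed-deterministic
    synthetic-data generators that emulate the study design and emit ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    pracma,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
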