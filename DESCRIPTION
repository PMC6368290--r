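Package: ccrwalk
Title: Reconstruction and Multi-Technology Benchmarking of Complex
    Chromosomal Rearrangements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the analysis of complex chromosomal rearrangements
    (CCRs) from structural-variant call sets produced by heterogeneous
    technologies (paired-end and mate-pair short-read WGS, linked reads,
    optical maps, aCGH).  Junction endpoints are clustered into
    breakpoints, breakpoint junctions are analysed at the nucleotide
    level (microhomology, non-templated insertions, repeat context),
    derivative chromosomes are reconstructed by walking a breakpoint
    graph and emitted as molecular karyotype strings, and call sets are
    compared by a Jaccard/breakpoint-distance similarity criterion with
    frequency-based filtering and ranking.  A simulator generates
    chromothripsis-like rearrangements with known truth together with
    per-technology call emulators, so detection rate, false-negative
    rate and breakpoint resolution can be benchmarked without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
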