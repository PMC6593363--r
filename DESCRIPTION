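Package: cnvrdb
Title: Copy Number Variant Region Construction and Characterization from
    Multi-Sample Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dataset-wise pipeline for turning multi-sample window read
    counts from whole-genome sequencing into copy number variant regions
    (CNVRs) with per-sample integer copy-number genotypes. Includes a
    simplified multi-sample read-depth caller (1 kb windows, three
    adjacent significant windows per call), sample quality control (PCA
    outliers on normalized counts, 1.5 x IQR rules on deletion proportion
    and total calls), CNVR construction by 50% pairwise reciprocal
    overlap, rule-based CNVR genotype assignment with CN2-to-CN_
    correction, Hardy-Weinberg and parity tests on diallelic CNVR
    genotypes, Spearman/ward.D2 sample clustering, gene/QTL/gap/repeat
    annotation, a synthetic multi-breed cohort simulator with known
    truth, and generation of a self-contained interactive HTML CNVR
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), ape, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
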