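Package: methylDMR
Title: Context-Aware Detection of Differentially Methylated Regions from
    Bisulfite Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) between two
    bisulfite-sequencing samples in CpG, CpHpG and CpHpH contexts from
    Bismark-style CX reports. Three interchangeable calling engines are
    provided (per-cytosine neighbourhood, tiling bins, and a kernel
    noise filter that smooths methylated and total read counts), with
    Fisher's exact test or a two-proportion score test on pooled counts
    and a beta-regression test for biological replicates, followed by
    Benjamini-Hochberg correction, iterative merging and size filtering.
    A scrambled-methylome procedure selects the window/bin size and a
    spatial-correlation diagnostic indicates whether kernel smoothing is
    appropriate for a given methylation context. A synthetic-methylome
    generator with planted DMRs supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
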