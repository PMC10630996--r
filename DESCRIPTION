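Package: ejcmap
Title: Exon-Level Mapping of Exon Junction Complex Deposition from eCLIP
    and RIP Read Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects exon junction complex (EJC) binding at single-exon
    resolution from truncation-based eCLIP data and from protein-protein
    crosslinking RIP ('ipaRt'-style) coverage. Implements the stop rate
    difference (SRD) statistic with replicate-integrated chi-square
    testing against merged size-matched input controls, a windowed
    median-coverage enrichment score with an empirical threshold
    calibrated on last exons, meta-exon profiling of read 5' ends and
    midpoints, expression- and uridine-content bias stratification,
    two-method integration with peak-set Jaccard agreement, and a seeded
    synthetic read generator with known per-exon deposition for
    end-to-end validation.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
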