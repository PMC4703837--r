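Package: madzyd
Title: Maternal and Zygotic Definition of Chromatin Features from
    Transcription-Blocked Embryo ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies chromatin features (H3K4me3, H3K27me3, p300 binding)
    as maternally defined (MaD) or zygotically defined (ZyD) by comparing
    ChIP-seq enrichment in alpha-amanitin-injected (transcription-blocked)
    versus control embryos. Implements MA-based two-sample normalization with
    an Audic-Claverie count statistic, per-replicate change calls and
    cross-replicate consensus labels, gene-level classification with
    promoter windows and GREAT-style regulatory domains, enhancer-cluster
    stitching with a ranked-signal elbow cutoff and hypergeometric
    enrichment, motif-activity inference by ridge regression, promoter
    DNA-methylation logic, and chromatin-state transition accounting.
    A synthetic-data module plants ground truth so the whole analysis runs
    and is verified without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
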