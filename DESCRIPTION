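Package: epromoter
Title: Epromoter Identification and Pleiotropy Analysis from STARR-Seq Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies promoters with enhancer activity (Epromoters) from
    (Cap)STARR-seq coverage by FPKM normalisation, fold-change ranking and
    knee-point thresholding, then quantifies the pleiotropic association of
    Epromoter variants with GWAS traits. Provides expression-matched control
    promoter selection via the tau tissue-specificity index, LD expansion of
    GWAS lead SNPs from a phased haplotype panel, non-redundant trait counting
    per promoter, eQTL proximal/distal target classification, consistency with
    promoter-promoter 3D interactions, a CRISPRi distal-regulation screen, and
    integration of four evidence layers into a final pleiotropic variant list.
    A synthetic-data generator plants known Epromoters, distal targets and
    pleiotropic variants so that the full pipeline can be exercised and its
    recovery measured without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
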