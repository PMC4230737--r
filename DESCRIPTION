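Package: methaberr
Title: Classification and Enrichment of DNA Methylation Aberrations in
    Reprogrammed Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects, classifies and interprets DNA methylation aberrations
    in induced pluripotent stem cells (iPSCs) relative to their parental
    fibroblasts and reference embryonic stem cells, from beta-value
    methylation array data. Implements per-probe delta-beta differential
    methylation with Wilcoxon rank-sum tests and Benjamini-Hochberg FDR,
    a four-class aberration taxonomy (de novo methylation, failed
    methylation, failed demethylation, de novo demethylation),
    permutation-based enrichment of aberrant CpGs and genes at
    transcription-factor binding regions with exact plus-one p-values,
    CpG-island-context and TSS-distance profiling, RRBS-array concordance,
    tumour-versus-normal delta-beta profiling, and a synthetic beta-value
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
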