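Package: mmes
Title: Maximum-Minimum Exon Score Screening for Tumor-Specific Alternative Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate tumor-specific alternative-splicing events from
    exon-level expression matrices using the Maximum-Minimum Exon Score (MMES):
    log2 probeset signals are normalized to the normal-cohort mean, aggregated
    to exon-level means, and each gene is scored per tumor by the range
    (maximum minus minimum) of its exon signals, so that genes whose exon
    subsets move differently from the rest of the gene rank highly while
    uniform whole-gene expression changes score zero. Includes the downstream
    visual-screening plot builders (cohort and per-tumor gene plots with exon
    tracks and one-standard-deviation deviation histograms), qPCR validation
    statistics (standard-curve absolute quantification, splicing index, Welch
    two-sample comparison), and a synthetic exon-array cohort simulator with
    recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
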