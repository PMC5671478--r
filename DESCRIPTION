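Package: stableref
Title: Reference Gene Discovery and Validation from Transcriptome and RT-qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering, validating and using reference (housekeeping)
    genes. Screens transcript-by-sample expression matrices genome-wide for
    constitutive, stably expressed transcripts using coefficient-of-variation,
    maximum-fold-change and log-CV filters; ranks RT-qPCR candidate genes with
    geNorm, NormFinder, BestKeeper and the comparative delta-Ct method and
    aggregates them into a geometric-mean consensus; estimates the optimal
    number of reference genes by pairwise variation; and re-normalizes
    expression matrices against chosen reference genes for fold-change based
    differential-expression calls. Includes synthetic data generators with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
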