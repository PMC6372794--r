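Package: barseqfit
Title: Fitness Profiling of Barcoded Transposon Libraries Under Serial
    Passage Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Genome-wide fitness analysis of randomly barcoded transposon
    mutant libraries (BarSeq) subjected to serial-passage selection, such
    as the depletion of adhesive cells by submerged cheesecloth.  Provides
    a forward simulator of pooled passaging experiments with planted
    phenotype classes, barcode extraction and counting from FASTQ reads,
    log2-ratio strain fitness with weighted gene-level aggregation,
    temporal profile construction with replicate-noise filtering and
    growth-defect normalization, ranking, hierarchical clustering,
    cofitness analysis, and rule-based labeling of temporal archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
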