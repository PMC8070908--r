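Package: bsaseqr
Title: Bulked Segregant Analysis Mapping from Pooled Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for QTL-seq style bulked segregant analysis (BSA-Seq) of
    an F2 population: variant filtering, per-bulk SNP-index and
    delta(SNP-index) computation oriented to a parental allele,
    sliding-window aggregation with per-chromosome LOESS smoothing,
    empirical-tail and fixed significance thresholds, candidate-region
    extraction with single-site flanking, gene-model intersection and GO
    term tallies. Includes a Mendelian F2 bulk-sequencing simulator for
    validating the whole chain, plus segregation-ratio chi-square tests
    and 2^-ddCt relative-expression analysis for qRT-PCR follow-up.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
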