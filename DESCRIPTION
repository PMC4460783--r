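Package: mirTRS
Title: Detecting miRNA Regulatory Activity by Target Running-Sum Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based detection of microRNA regulatory activity from matched
    miRNA and mRNA expression profiles of the same samples. Genes are ranked by
    Spearman correlation with a miRNA, and a prediction-confidence-weighted
    running-sum enrichment score over the ranked list measures whether the
    miRNA's sequence-predicted targets concentrate at either end of the list.
    Significance is assessed by a gene-label permutation null with
    Benjamini-Hochberg control of the false discovery rate across miRNAs.
    Includes TargetScan context-score aggregation into weighted target sets,
    microarray/sequencing preprocessing steps (asinh + quantile normalization,
    low-signal filters, batch correction, replicate averaging), leading-edge
    extraction with hypergeometric annotation-category enrichment, and a
    synthetic-data generator with planted regulators for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
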