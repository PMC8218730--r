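Package: ssmtx
Title: Differential Expression and Contamination QC for Sorted Lymph Node
    Macrophage Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for bulk RNA-seq of sorted lymph node
    macrophage subsets (sub-capsular sinus vs medullary sinus macrophages)
    profiled in a pooled 4 x 2 x 2 factorial design (pool, tumor-draining
    status, CD11c phenotype). Implements gene filtering, median-of-ratios
    size factors, per-gene negative binomial generalized linear models
    with likelihood-ratio tests and Holm adjustment, cross-platform
    (RNA-seq vs microarray) harmonization by probe aggregation,
    intersection and per-sample standardization, and lymphocyte
    contamination scoring against immune lineage marker signatures with
    exact Mann-Whitney comparisons. Ships a synthetic-data generator that
    emulates the study design with controllable lymphocyte contamination,
    for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
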