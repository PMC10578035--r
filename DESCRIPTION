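Package: tregfinder
Title: Identification of Total RNA Expression Genes from Single-Cell and
    Single-Nucleus RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate total RNA expression genes (TREGs): genes
    whose within-cell expression rank is stable across cells and cell types
    and whose expression therefore tracks a cell's or nucleus's total RNA
    content. Implements expression and proportion-zero filtering of sparse
    count matrices, the rank-invariance score, per-gene linear models of
    expression against log2 total counts, standardized regression slopes
    over ordered cell types for cross-assay comparison with smFISH puncta
    counts, downstream analysis of per-nucleus segmentation tables, and
    cross-condition stability reports. Includes a synthetic-data generator
    with planted rank-invariant genes so the whole workflow is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    scater
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
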