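Package: uscore
Title: Rank-Based Gene Signature Scoring for Single-Cell Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-cell scoring of gene signatures in sparse single-cell
    expression matrices using the Mann-Whitney U statistic on capped gene
    ranks. Signatures may combine positive and negative gene sets (+/-
    suffix convention, GMT files); genes absent from the matrix are either
    imputed as zero counts or skipped, reflecting whole-transcriptome
    versus targeted-panel assays. Matrices are processed in cell chunks
    with results independent of chunking and worker count. Optional
    k-nearest-neighbour smoothing averages scores over neighbouring cells
    in a PCA (or user-supplied) embedding with geometric decay weights,
    and scores can be aggregated to per-sample means for sample-level
    statistics. Includes a negative-binomial simulator that plants
    signature-positive cell populations for end-to-end validation, readers
    for Matrix Market triplet and dense delimited matrices, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    optparse,
    parallel
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
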