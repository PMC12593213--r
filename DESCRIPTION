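Package: scStratify
Title: Retrospective Stratification of Untreated Cells by Similarity to
    Treatment Survivors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for survivor-bias-aware analysis of two-arm single-cell
    expression experiments in which the treated arm contains only cells that
    survived treatment. Untreated control cells are ranked by their
    transcriptional distance (minimal cosine distance in PCA space, by
    default) to treated survivor cells and labeled predicted-sensitive or
    predicted-resistant at a cutoff percentage; the cutoff is selected by
    sweeping the percentage grid and scoring predicted-sensitive versus
    treated separability with balanced accuracy of a multilayer-perceptron
    classifier under repeated stratified splits. Discriminative genes are
    ranked by plug-in mutual information between discretized expression and
    the binary labels under a minimum-bin-occupancy constraint. Includes a
    negative-binomial synthetic-data generator with a planted
    sensitive/resistant mixture and survivor-biased treated arm, so every
    stage is testable against ground truth, plus CSV ingest with cell-level
    quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Seurat,
    optparse,
    withr
Config/testthat/edition: 3
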