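Package: momnet
Title: Multi-Omic Differential Analysis and Partial-Correlation Networks
Version: 0.2.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for two-group multi-omic (metabolomics + proteomics)
    cohort analysis: missingness filtering, probabilistic quotient
    normalization, log2 transformation, k-nearest-neighbor imputation and
    duplicate-assay averaging; per-molecule linear-model association testing
    with Benjamini-Hochberg correction and a signed significance score;
    pathway-level filtering of differential results; Gaussian graphical model
    inference via analytic shrinkage of the correlation matrix with
    FDR-controlled edge selection; seed-based subnetwork extraction; and a
    synthetic cohort generator with planted ground truth (sparse precision
    matrix, group shifts, outcome effects, dilution factors, missingness) so
    that every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
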