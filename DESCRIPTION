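Package: refstab
Title: Reference-Gene Stability Validation and Relative Quantification for qRT-PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating candidate reference (housekeeping) genes from
    quantitative real-time PCR quantification-cycle (Cp/Cq) data and for
    normalizing target-gene expression against them. Implements the geNorm
    expression-stability value M with stepwise gene exclusion, normalization-factor
    pairwise variation (V) and the 0.15 cut-off rule for choosing how many
    reference genes to use; the NormFinder model-based stability value with
    intragroup variance estimation and shrunken intergroup deviations;
    amplification-efficiency standard curves from dilution series; relative
    quantities Q = 2^(minCp - Cp); multi-gene normalization factors (geometric
    means); and relative expression by the 2^-ddCp method summarized over
    biological replicates. A synthetic Cp-data generator reproduces the design of
    a multi-tissue, multi-stress reference-gene survey (candidate genes over
    tissue, abiotic- and biotic-stress sample subsets with biological and
    technical replicates) and provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
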