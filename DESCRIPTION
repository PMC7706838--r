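Package: erydecon
Title: Stage-Resolved Proteome Simulation and In Silico Mixture Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for benchmarking reference-based deconvolution of ordered
    cell-maturation stages from bulk proteome intensity matrices. Includes a
    synthetic-data generator for stage-resolved DIA-style proteomes with known
    ground truth (temporal co-expression archetypes, log-normal replicate
    noise, intensity-dependent dropout, declining histones, planted marker
    proteins), preprocessing (completeness filtering, downshifted-normal
    imputation), an S0-regularized multi-stage ANOVA with permutation-based
    FDR, hierarchical clustering of z-scored temporal profiles, marker-panel
    assembly, signature-matrix construction, iterative non-negative
    least-squares estimation of mixing fractions with outlier-marker
    retention, an ordinal earth-mover error metric with baseline controls,
    and histone proteomic-ruler copy-number estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
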