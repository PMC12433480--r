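Package: viroscore
Title: Susceptibility Scoring of Tumor Cell Lines to Oncolytic Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the susceptibility of cancer cell lines to
    oncolytic-virus-mediated growth inhibition from live-cell-imaging time
    series. Confluence curves are baseline-normalized, summarized by
    trapezoidal area under the curve (AUC), and normalized to the untreated
    condition; per-line dose-response inference uses one-way ANOVA with
    Dunnett's many-to-one multiple comparisons to derive a rank multiplier,
    which combines with the AUC sum into a composite susceptibility score
    and cell-line ranking. Bulk RNA-seq count matrices are normalized with
    a median-of-ratios size-factor estimator, log-transformed and scaled,
    and per-gene expression is correlated with the susceptibility ranking
    (Spearman with exact small-n permutation inference, plus Pearson).
    Also included: four-parameter logistic and hyperbolic standard-curve
    calibration with out-of-range substitution rules, plaque-assay titer
    computation, and a seeded synthetic-data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    mvtnorm,
    multcomp,
    DESeq2,
    Matrix
Config/testthat/edition: 3
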