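Package: dcmarker
Title: Differential-Correlation Biomarker Discovery for Two-Class Expression Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential correlation analysis for case/control molecular
    expression panels, aimed at plasma microRNA qPCR studies. Implements
    qPCR crossing-point (Cp) filtering and global-mean normalization,
    exhaustive ranking of molecule pairs by the absolute difference of
    per-class Spearman correlations, a profile likelihood-ratio test for
    equality of two normal-scores (van der Waerden) rank correlations,
    evaluation of marker pairs and pair combinations by logistic regression
    with interaction terms and in-sample ROC/AUC, a Welch t-test single
    molecule baseline, class-specific correlation-network export, and a
    Gaussian-copula synthetic-data generator with planted differential
    pairs, mean shifts and quality-control artifacts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
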