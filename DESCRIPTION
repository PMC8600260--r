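Package: comprev
Title: Compensation and Reversion Analysis of Three-Strain RNA-Seq
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Differential-expression and compensation analysis for a
    three-group strain design: a derived strain, its progenitor, and a
    strain back-selected from their hybrids. Implements a self-contained
    negative-binomial quasi-likelihood F-test (TMM normalization, logCPM,
    Cox-Reid adjusted-profile-likelihood dispersion estimation with
    empirical-Bayes moderation), the per-gene compensation-coefficient
    statistic on group-mean logCPM with its compensated /
    overcompensated / uncompensated classification, log-fold-change
    concordance between contrasts, kernel-density summaries, Fisher's
    exact gene-set enrichment over GMT collections, Venn partitions of
    DEG sets, and a negative-binomial count simulator with known
    per-gene compensation classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
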