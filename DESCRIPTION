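Package: fpicpi
Title: Ferroptosis and Cuproptosis Potential Indices from Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ferroptosis and cuproptosis activity in bulk and
    single-cell transcriptomes through gene-set potential indices. A
    single-sample gene set enrichment (ssGSEA) engine scores directional
    gene-set pairs, and the normalized difference between positive- and
    negative-component enrichment defines the Cuproptosis Potential Index
    (CPI) and the Ferroptosis Potential Index (FPI). Supporting stages cover
    empirical-Bayes moderated differential expression with fold-change and
    FDR gates, weighted co-expression network module detection with
    topological overlap, Kaplan-Meier and log-rank prognosis on
    expression-dichotomized cohorts, per-cell index scoring with subcluster
    contrasts, and seeded synthetic-data generators that emulate the
    assumed study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Matrix,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
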