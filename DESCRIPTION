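Package: coprescribenet
Title: Co-Prescription Network Analysis of Opioid Doctor Shopping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-patient co-prescription networks from longitudinal
    opioid claims, where a tie between two patients is weighted by the number
    of unique prescribers they share within a pooled three-quarter window.
    Computes network-prominence metrics (weighted PageRank with percentile and
    z-score transforms, degree, bipartite Co-HITS scores), derives quarterly
    opioid-risk outcomes (prescription counts, maximum daily morphine milligram
    equivalents, overdose and opioid use disorder diagnosis flags), decomposes
    prominence into between-person and within-person components, and fits
    random-intercept logistic and negative-binomial panel models with state
    fixed effects, intraclass correlations and predicted margins. Ships a
    seeded synthetic claims generator emulating the statistical structure of
    commercial claims data so the whole pipeline is testable without access to
    proprietary records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    lme4,
    glmmTMB,
    pracma,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr
Config/testthat/edition: 3
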