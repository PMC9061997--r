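Package: icpattern
Title: Immune Checkpoint Regulation Patterns and ICscore for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers immune checkpoint regulation patterns in bulk
    expression cohorts by resampling-based consensus clustering over a fixed
    31-gene costimulatory/coinhibitory panel, derives pattern-associated
    signature genes, and summarizes each sample with a PCA-based immune
    checkpoint score (ICscore). Includes empirical-Bayes location-scale
    batch correction, single-sample rank-walk gene-set enrichment (ssGSEA)
    with ESTIMATE-style stromal/immune scores, Kaplan-Meier, log-rank and
    Cox proportional-hazards survival analysis with a maximally selected
    log-rank cutpoint, mutation-landscape summaries (tumor mutation burden,
    mutation frequency and co-occurrence, copy-number gain/loss frequency),
    and a linked synthetic-cohort generator so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
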