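Package: flymetnet
Title: Metabolic Network Construction, Multi-Omics Overlay, and Feeding
    Behavior Analytics for Drosophila
Version: 0.1.0
Authors@R:
    person("flymetnet", "maintainers", email = "flymetnet@example.org",
           role = c("aut", "cre"))
Description: Builds compound, compound-reaction, compound-gene, and
    compound-reaction-enzyme-gene network graphs from a flat-file metabolic
    pathway database, overlays differential metabolomics and transcriptomics
    results onto them as renderer-agnostic visual attributes, performs
    hypergeometric pathway over-representation analysis with false discovery
    rate control, runs a complete metabolomics differential-statistics
    pipeline (missing-value filtering, half-minimum imputation, range
    scaling, Welch's t-test, one-way ANOVA, RSD quality control, Ward
    clustering, PCA with group confidence ellipses), and detects and
    summarizes feeding bouts from 5 Hz fly-to-food interaction signals with
    stratified BCa bootstrap and randomization statistics. Deterministic
    synthetic-data generators make every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
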