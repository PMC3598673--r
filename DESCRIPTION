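Package: hqsar
Title: Heuristic Best-Subset QSAR Modelling of BCRP Substrate Uptake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates linear quantitative structure-activity
    relationship (QSAR) models of substrate uptake by BCRP-482 polymorphs.
    Implements heuristic descriptor preselection (completeness, variance and
    intercorrelation screens), an incremental best-subset multiple linear
    regression search with the classical fit statistics (coefficients with
    standard errors and t values, R-squared, s-squared, F, leave-one-out
    Q-squared), external validation by absolute relative error, a seeded
    synthetic descriptor-matrix generator for support-recovery benchmarking,
    and a bundled Mitoxantrone uptake dataset for the 482R/482G/482T
    polymorphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
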