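Package: savrdemand
Title: Demographic Projection of Surgical Aortic Valve Replacement Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prevalence-based forecasting of surgical aortic valve
    replacement (SAVR) volumes from municipality-level census panels.
    Validates and aggregates census age-structure tables, computes aging and
    longevity indices with nonparametric across-year comparison
    (Kruskal-Wallis omnibus, tie-corrected Dunn post hoc with Bonferroni
    adjustment), estimates geometric growth rates and doubling times,
    projects populations under two-phase decreasing-rate and stagnation
    scenarios, and translates projected elderly populations into expected
    surgical volumes via a decade-prevalence estimator. Includes a synthetic
    census/registry generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
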