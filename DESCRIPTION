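Package: scorewalk
Title: Norming Pipelines for Summed Likert-Scale Instruments
Version: 0.1.0
Authors@R:
    person("Scorewalk", "Maintainers", email = "maintainers@scorewalk.example.org",
           role = c("aut", "cre"))
Description: Converts raw summed scores from ordinal questionnaires (exemplified
    by the 12-item MANSA quality-of-life scale) into common metrics against a
    reference group: linear T-scores, Rankit (rank-based inverse normal)
    T-scores, and IRT-based T-scores from a multigroup graded response model
    with EAP scoring. Fits closed-form raw-score to T and raw-score to
    percentile-rank conversion formulas, builds rounded crosswalk tables,
    computes Jacobson-Truax reliable-change and clinical-significance
    thresholds, and quantifies between-method agreement with two-way
    absolute-agreement ICCs and Bland-Altman limits. Includes a graded-response
    simulator so the whole pipeline is testable without access to raw
    normative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
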