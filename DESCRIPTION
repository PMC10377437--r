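Package: pvte
Title: Thromboembolic Risk Modelling for Hydroxyurea-Treated Polycythemia Vera Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study thromboembolic-event (TE) risk in polycythemia vera
    cohorts abstracted from electronic health records. Provides a patient-level
    cohort data model with eligibility filtering, a synthetic cohort generator
    with planted hazard structure for end-to-end testing, period-aligned
    annualized incidence rates with propensity-score matching, Kaplan-Meier and
    k-group log-rank utilities, a random survival forest risk model with
    drop-column variable importance and windowed ROC-AUC evaluation, a pairwise
    synergy screen contrasting expected and observed log-rank significance of
    two-variable splits, and a two-variable threshold search ("risk landscape")
    from which clinical decision trees are derived and validated on independent
    cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
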