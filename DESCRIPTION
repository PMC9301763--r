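Package: rxlines
Title: Line-of-Therapy Construction and Persistence Analysis for
    Dispensing Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Drug-utilisation analysis of longitudinal prescription
    dispensing claims, built around antidepressant treatment in
    pharmacy-claims data. Provides a molecule-to-class formulary, new-user
    cohort selection (index dispensing, washout, antipsychotic
    pre-exclusion, age filter), construction of numbered treatment lines
    from dispensing events (discontinuation gaps, class switches,
    combination and augmentation, dose-strength escalation), a
    self-contained Kaplan-Meier product-limit estimator with Greenwood
    variance, log-rank test and relative risk at a fixed horizon,
    treatment-free episode analysis, and prescribing-pattern summary
    tables. A synthetic dispensing-data generator with known ground-truth
    episode structure makes the whole pipeline testable without access to
    licensed claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
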