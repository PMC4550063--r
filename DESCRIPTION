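Package: anginacdss
Title: Chest-Pain Clinical Decision Support and Guideline-Concordance Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements a guideline-based clinical decision support engine
    for new-onset stable chest pain: three-question pain-typicality
    classification, risk-factor stratification, pre-test probability lookup
    from a packaged guideline table (NICE CG95), and rule-based investigation
    and medication recommendations, including an expert-panel rule for
    pre-test probabilities above 90 percent. Also provides the descriptive
    statistics used to audit clinic behaviour against the recommendations:
    concordance counts, Wald binomial confidence intervals, two-proportion
    difference intervals, medication-class delta classification, and a
    continuity-corrected two-proportion sample-size calculator. A synthetic
    cohort generator and clinic-pathway simulator allow the whole evaluation
    to run without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
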