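Package: switchbia
Title: Budget-Impact Analysis of Switching from Oral Antipsychotics to
    Aripiprazole-Depot in German Schizophrenia Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a single-cohort pre-post budget-impact analysis of a
    treatment switch from oral antipsychotics to a long-acting injectable
    (aripiprazole-depot) from the perspective of the German statutory health
    insurance. Provides a calibrated synthetic patient-cohort simulator,
    per-patient resource-utilization costing over thirteen cost categories
    with integer-cent arithmetic, prevalence-based national extrapolation
    with market-share scenarios, one-way deterministic sensitivity analysis
    with parameter ranking, paired nonparametric endpoint statistics
    (Wilcoxon signed-rank, one-sided binomial against an external reference
    rate), sample-size planning with dropout inflation, and report rendering
    with German or default number formatting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
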