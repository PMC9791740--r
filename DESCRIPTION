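Package: tkicea
Title: Decision-Tree and Markov Cohort Cost-Effectiveness Model for
    Tyrosine Kinase Inhibitors in Pediatric Ph+ ALL
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cost-effectiveness analysis of dasatinib versus imatinib as the
    added tyrosine kinase inhibitor in pediatric Philadelphia
    chromosome-positive acute lymphoblastic leukemia, from the Chinese health
    system perspective.  A decision tree covers the induction and intensive
    chemotherapy phases and feeds a 10-year annual-cycle Markov cohort model
    over maintenance, relapse, transplantation and death states.  Provides
    incremental cost-effectiveness ratios and net monetary benefit, one-way
    (tornado) sensitivity analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, a generic-drug-price scenario,
    threshold-price inversion by root finding, structural calibration against
    published totals, and a patient-level microsimulation generator that
    doubles as an independent oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
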