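Package: acmgrules
Title: ACMG/AMP Germline Variant Classification Rule Engine with VUS
    Subclassification
Version: 0.1.0
Authors@R:
    person("MAGI", "Engineering", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: A rule engine for germline sequence-variant interpretation.
    Assigns and strength-modifies ACMG/AMP evidence criteria from structured
    annotation records (in-silico predictor thresholds for PP3/BP4, PM2 and
    BP6 strength modification, the BP1 benign-missense rule, a graded PVS1
    loss-of-function decision tree and a 3% decision-MAF pre-filter),
    combines met criteria into the ACMG 2015 five-tier verdict, subclassifies
    variants of uncertain significance into Hot, Middle and Cold via an
    auditable pattern table, and applies an inheritance- and sample-aware
    pathogenicity-potential criterion (P_POT) to decide diagnostic
    reportability, with substitution of segregation criteria once family
    testing results arrive. Ships curated worked-example fixtures, a seeded
    synthetic annotation generator, JSON Lines/CSV readers, report writers
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
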