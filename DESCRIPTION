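Package: ewsbench
Title: Head-to-Head Evaluation of Ward Early Warning Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transparent scoring engines for the Modified Early Warning Score
    (MEWS), the National Early Warning Score (NEWS) and NEWS2, together with
    the evaluation protocol used to compare early warning scores on
    medical-surgical ward cohorts: deterioration-event labeling (ward death or
    direct ward-to-ICU transfer within a fixed horizon of a score),
    carry-forward alignment of irregularly sampled score streams to a dense
    reference stream, bootstrapped AUROC with one observation per encounter,
    DeLong paired comparison, NEWS-anchored threshold matching, observation-
    level test-characteristic tables, precision-recall and encounter-level
    efficiency curves, and trigger-to-event lead-time analysis. A synthetic
    multi-campus ward-EHR generator with known ground-truth risk makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    data.table,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
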