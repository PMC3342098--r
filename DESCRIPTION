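Package: algopath
Title: Virtual Evaluation of Clinical Decision Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encode clinical decision algorithms (serial, dichotomous
    flowcharts) in a declarative document format, route real or synthetic
    patient cohorts through them, and score each algorithm for fit,
    per-diagnosis and overall sensitivity, theoretical serial delay to
    management, and harm weighted by omission and commission error.
    Includes the Clinical Algorithm Nosology: the CASA structural
    complexity score and the CAPA pairwise patient-abstraction similarity
    scale, plus a synthetic cohort generator calibrated to a flowchart's
    own decision logic for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
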