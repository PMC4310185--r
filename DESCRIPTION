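Package: ehrtempo
Title: Multi-Resolution Temporal Feature Extraction from Hospital Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disease- and task-agnostic feature engineering for hospital
    administrative data. Timestamped entity events (diagnoses, admissions,
    emergency visits, medications) are discretized into per-entity count
    series and convolved with a one-sided multi-resolution filter bank to
    produce temporal features at assessment points. Includes vocabulary
    control via rare-event pooling and per-class dictionary caps, Elixhauser
    comorbidity baselines mapped from ICD-10 codes, unplanned-readmission
    labelling over multiple horizons, patient-and-time-disjoint
    derivation/validation splits, elastic-net readmission scoring with
    Mann-Whitney AUC confidence intervals, and a seedable synthetic EHR
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    glmnet,
    Matrix,
    methods,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
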