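Package: radgen
Title: Radiogenomic Marker Discovery from PET/CT Radiomics and Pathway-Level Mutation Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering prognostic radiogenomic markers in
    oncology cohorts. Implements tumor-only somatic variant filtering, pathway-level
    CADD disruption scoring, IBSI-style radiomic feature extraction from PET/CT
    volumes (including GLSZM texture and SUV metrics), survival-optimized
    dichotomization with minimum group-size constraints, radiomic-pathway
    association testing, combinatorial radiogenomic marker construction, and
    Monte Carlo cross-validated prognostic classification with feature-importance
    ranking. Ships a synthetic-cohort generator with planted effects so every stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    survival,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
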