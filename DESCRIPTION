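Package: mammodb
Title: Document-Oriented Management of Mammography Screening Data for AI Validation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An extract-transform-load toolkit for consolidating the four data
    components needed to validate artificial-intelligence computer-aided
    detection (AI-CADe) systems against breast-cancer screening programs:
    DICOM image metadata, radiologist double-reading assessments, national
    cancer-registry outcomes, and vendor AI inference results. Provides a
    minimal document store with group-by aggregation, a DICOM header indexer
    that never touches pixel data, hierarchy construction (image, series,
    study, patient) with an intersection-allow-missing-minority tag merge,
    pseudonymization with salted SHA-512/256 hashing and characteristic
    binning, Swedish personal-number validation and canonicalization,
    double-reading decision collapse, reference-standard labelling,
    case-control and cohort population selection, mammography input-case
    classification, vendor inference normalization, and a seeded synthetic
    fixture generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lubridate,
    parallel,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
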