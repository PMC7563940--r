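Package: bcmets
Title: Exponential Growth Kinetics and Metastasis Surveillance Windows for
    Breast Cancer Subtypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the natural history of a breast-cancer primary tumor and
    its secondary distant metastases under exponential volume growth, indexed
    by tumor volume doubling time (TVDT). Computes, per ER/PR/HER2/Ki-67
    molecular subtype, the non-visible and visible metastasis growth periods,
    post-surgery survival windows, chained diagnostic windows, a personalized
    multimodal-examination schedule, and the horizon after which a patient
    with no detected metastases may be considered healthy. Includes a
    two-measurement TVDT estimator, a subtype registry with per-band screening
    intervals, CSV/JSON patient-record I/O, an iCalendar exporter, and a
    synthetic patient-record generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
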