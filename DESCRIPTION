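Package: ritdose
Title: Preclinical Radioimmunotherapy Dosimetry and Radioligand Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for preclinical antibody radioimmunotherapy
    studies: Lindmo immunoreactive-fraction estimation, homologous
    competitive-binding affinity fits, internalization time-course
    fractions, decay-corrected and body-weight-normalized biodistribution
    tables (%ID/g), MIRD-style tumor absorbed-dose estimation from
    surrogate-nuclide time-activity curves, tumor growth-response
    classification, and seeded synthetic-data generators with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
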