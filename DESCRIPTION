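Package: snoglyc
Title: Non-Targeted, Isomer-Sensitive N-Glycome Analysis from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-targeted N-glycomics from PGC-LC-MS/MS data.
    Implements diagnostic oxonium-ion profiling of MGF tandem mass spectra,
    SNOG and extended-SNOG (eSNOG) spectral scoring and filtering, aggregation
    of charge-deconvoluted MS1 features into quantitative precursor-mass
    histograms, in-silico enumeration of canonical N-glycan compositions for
    mass annotation, eSNOG-based sub-structural stratification including rare
    epitope screens, Man5-normalized isomer elution profiling, and cross-sample
    correlation and clustering. Ships a seeded synthetic-data generator so the
    entire pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
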