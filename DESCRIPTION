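Package: skiff
Title: Query FHIR Servers and Assemble Tabular Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A data-collection toolkit for clinical research on FHIR (Fast
    Healthcare Interoperability Resources) servers. Builds authenticated HTTP
    sessions, runs paginated and time-partitioned searches, evaluates a
    documented FHIRPath subset to flatten arbitrarily nested resources into
    tabular datasets, triages free-text clinical documents with regular
    expressions, and bulk-downloads DICOM studies referenced by ImagingStudy
    resources from a DICOMweb endpoint. Ships a deterministic synthetic
    FHIR/DICOMweb store and in-process mock server so every pipeline step is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    curl,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
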