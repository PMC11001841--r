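Package: omopmri
Title: Harmonization of Public Breast-Cancer MRI Datasets to an OMOP-Coded Common Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a single, fully coded clinical dataset from
    heterogeneous public breast-cancer collections, and for technique-aware
    selection of the matching MRI series. Ships a common data model (CDM) of
    OMOP-coded concepts with curated value sets, declarative per-dataset
    mapping specifications, and a repeatable extract-transform-load (ETL)
    engine that cleans messy source values (free-text tumor positions,
    concatenated medications, mixed-granularity TNM categories) into
    registered concept codes with no missing cells. A DICOM-metadata layer
    classifies imaging series by MRI technique (dynamic contrast-enhanced,
    diffusion-weighted, anatomical) and orientation from sparse tag records,
    decodes diffusion b-values including the GE private-tag encoding, and
    writes NBIA Retriever manifests for downloading selected series.
    Seeded synthetic-fixture generators emulate each source schema with
    known ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
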