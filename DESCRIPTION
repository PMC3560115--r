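Package: xrepo
Title: Dynamically Extensible Repository Engine for Multidisciplinary
    Clinical Research Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An embeddable research-data repository engine in which data
    types are defined at runtime rather than compiled into the database
    schema. Users author typed metadata schemas (groups of attributes and
    repeatable loops), attach conforming data instances to subjects and to
    a hierarchical process-event provenance taxonomy, and persist
    everything in a dual representation: a canonical XML document per
    instance plus flattened entity-attribute-value rows for dynamic
    querying. Includes ontology-assisted attribute naming from OBO term
    lists, group-based access control with field-level masking of personal
    data, a biosample freezer-inventory tracker with x-y box coordinates
    and courier shipment history, automatic metadata extraction from DICOM
    headers with modality-dependent event creation, a seeded synthetic
    Alzheimer-study cohort generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
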