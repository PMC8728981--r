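Package: mitschema
Title: Modular Minimum-Information Metadata Schema Tools for Nanosafety
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with a modular minimum-information metadata
    schema for nanosafety experiments. Provides the bundled six-module
    reference schema of labeled fields (grouping and content-bearing),
    serialization to CSV, JSON and XML, extension profiles for new approach
    methodologies (air-liquid interface, advanced intestine, 3D skin),
    validation and completeness scoring of experiment metadata records,
    deterministic crosswalk construction against flat controlled
    vocabularies (normalized exact matching, token-subset partial matching,
    curated overrides), coverage statistics per module and field category,
    synthetic fixture generators with planted ground truth, and export of
    records to an ISA-TAB-like four-table layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
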