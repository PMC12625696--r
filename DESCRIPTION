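Package: taxprofileQC
Title: Benchmarking Taxonomic Profiles Against Mock-Community Reference Reagents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evaluates taxonomic relative-abundance profiles against a known
    mock-community (reference reagent) composition using four key reporting
    measures: sensitivity, false-positive relative abundance (FPRA), observed
    diversity, and Bray-Curtis similarity. Supports 16S rRNA gene copy-number
    adjustment, rarefaction of count profiles, calibration of Minimum Quality
    Criteria (MQC) from a multi-laboratory cohort via quartile thresholds, and
    pass/fail assessment of data sets against those criteria. Includes a
    synthetic mock-community simulator (dropout, misclassification and
    false-positive noise) so every stage is testable without sequencing data,
    plus readers for plain, MetaPhlAn-style and QIIME-style profile tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools
Suggests: testthat (>= 3.0.0), withr, vegan, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'taxa.R'
    'measures.R'
    'io.R'
    'calibration.R'
    'rarefy.R'
    'synthetic.R'
    'fixtures.R'
    'cli.R'
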