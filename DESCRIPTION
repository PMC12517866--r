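Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A case/non-case pharmacovigilance pipeline for FAERS-style
    spontaneous adverse-event reports. Reads the quarterly "$"-delimited
    ASCII tables (DEMO, DRUG, REAC, THER, OUTC), removes duplicate case
    versions by the FDA-recommended rule, builds primary-suspect drug
    cohorts against an ATC dictionary, defines cases at the MedDRA system
    organ class level, and screens drug-event pairs with the reporting
    odds ratio and the BCPNN information component under a dual signal
    criterion. Includes sex/age subgroup and cross-stratified analyses,
    time-to-onset summaries, and a synthetic FAERS generator with planted
    reporting-odds multipliers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
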