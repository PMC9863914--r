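Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style spontaneous-report
    databases: reads and deduplicates quarterly ASCII or simplified TSV report
    tables, maps MedDRA preferred terms to standardised MedDRA queries (SMQs)
    and system organ classes, and screens drug-event pairs with
    shrinkage-corrected information component (IC) and reporting odds ratio
    (ROR) statistics with 95 percent intervals and signal classification.
    Includes time-to-onset and outcome summaries and a synthetic report
    generator with known ground-truth association ratios for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, data.table
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
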