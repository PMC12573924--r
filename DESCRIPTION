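Package: cifaudit
Title: Quality-Metric Auditing for Small-Molecule Crystallographic CIFs
Version: 0.1.0
Authors@R:
    person("cifaudit", "maintainers", email = "cifaudit@example.org",
           role = c("aut", "cre"))
Description: Extracts refinement-quality data items from Crystallographic
    Information Files (CIF 1.1), curates them with explicit validity rules
    (missing / malformed / bounded / out-of-range accounting), classifies
    entries along six structure-category axes (chemistry, disorder, radiation
    source, pressure, polymeric, refinement type), derives resolution from the
    Bragg equation and residual-density DTEST thresholds, assigns
    checkCIF-style A/B/C alert levels, and computes cohort distribution
    summaries and per-entry percentile context. Ships a seeded synthetic CIF
    corpus generator with exact injection quotas and ground-truth labels so
    the whole pipeline is testable without access to a licensed structure
    archive.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
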