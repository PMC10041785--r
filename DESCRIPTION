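Package: aedisparity
Title: Host-Factor Disparity Tests for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects drug-host factor interactions (sex or age disparities
    in adverse-event reporting) in spontaneous reporting databases such as
    FAERS. Provides four disparity tests on 2x2 host-factor contingency
    tables: a likelihood ratio test with a Monte-Carlo null, a normal
    approximation test of group proportions, and delta-method tests based on
    the proportional reporting ratio (PRR) and reporting odds ratio (ROR).
    Family-wise error is controlled with a Max-Stat step-down procedure and
    false discovery rate with Benjamini-Hochberg. Includes report-level
    ingestion with the standard preprocessing filters, composite-event
    mapping for MedDRA Preferred Terms, a synthetic report generator, and a
    simulation harness estimating empirical FWER, FDR and sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
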