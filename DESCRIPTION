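Package: faersror
Title: Reporting Odds Ratio Signal Detection for FAERS Quarterly Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for pharmacovigilance disproportionality analysis of
    FDA Adverse Event Reporting System (FAERS) quarterly ASCII extracts.
    Reads the $-delimited DEMO/DRUG/REAC/OUTC/INDI tables, curates the case
    universe (case-version deduplication, event-date windowing, INN and
    brand-name drug matching restricted to primary-suspect reports),
    computes Reporting Odds Ratios with Wald 95% confidence intervals for
    every drug-event pair, and flags potential safety signals (frequency
    >= 3 with lower confidence limit > 1, with a 99.9 sentinel when the
    comparator event count is zero). Includes descriptive reporter, outcome
    and indication tables, System Organ Class aggregation, per-signal case
    drilldowns, and a synthetic FAERS-format generator with analytically
    known reporting odds ratios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
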