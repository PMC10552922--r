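Package: hitsignal
Title: Pharmacovigilance Signal Detection and Case-Series Analytics for
    Heparin-Induced Thrombocytopenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying heparin-induced thrombocytopenia (HIT)
    reported under low-molecular-weight heparins. Reads, deduplicates and
    normalizes FAERS-style quarterly report tables, matches the HIT MedDRA
    preferred terms, and computes disproportionality statistics on
    drug-event 2x2 contingency tables: proportional reporting ratio (PRR),
    reporting odds ratio (ROR), chi-square with optional Yates correction,
    log-scale Wald confidence intervals, and the standard dual screening
    rules (PRR > 2 with chi-square > 4 and N > 2; ROR CI lower bound > 1
    with N > 2). Includes an inverse oracle that reconstructs integer
    contingency cells from published summary statistics, a structured
    43-case literature series with the Warkentin 4Ts pretest score, and a
    seeded synthetic report generator with known ground-truth odds ratios
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
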