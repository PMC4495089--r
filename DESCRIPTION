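Package: gpcost
Title: Micro-Costing of French General-Practice Consultations and Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based micro-costing pipeline for French general-practice
    visits under the 2008 tariff system. Attributes consultation and drug
    prescription costs to Social Security, to the patient and/or supplementary
    health insurance (remaining cost), and to total health expenditure,
    following the statutory rules in force in 2008: sector 1/2 consultation
    tariffs reimbursed on the contractual base, the 1 euro per-consultation
    lump sum for adults, long-duration disease (ALD/DLD) 100 percent coverage,
    drug reimbursement tiers (0/35/65/100 percent) and the 0.25 euro per-box
    franchise. Includes a seeded synthetic-cohort generator emulating the EPI3
    cross-sectional survey structure, group-comparison statistics (descriptive
    tables, chi-squared tests, one-way ANOVA with pairwise contrasts against a
    reference group), and a one-shot pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
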