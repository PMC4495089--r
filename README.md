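# gpcost

Micro-costing of French general-practice consultations and drug
prescriptions under the 2008 statutory tariff system, for health
economists and pharmacoepidemiologists comparing prescribing practices
(conventional, mixed, homeopathic) across payer perspectives.

Every visit is decomposed into a 3 x 3 cost grid:

|                    | Social Security | Remaining (patient + suppl. insurance) | Health expenditure |
|--------------------|-----------------|----------------------------------------|--------------------|
| **Consultation**   | share of the 22 EUR contractual base (70%, 100% for DLD), net of the adult 1 EUR lump sum | tariff − SS share, incl. the 10 EUR sector-2 excess | 22 EUR (sector 1) / 32 EUR (sector 2) |
| **Prescription**   | Σ max(0, tier x price x boxes − 0.25 EUR x boxes) | total − SS | Σ price x boxes |
| **Total**          | sum            | sum                                    | sum                |

with tiers 0/35/65/100%, a 100% rate for lines related to a long-duration
disease (DLD/ALD), and "Not under agreement" consultations uncosted
(`consultation_costed = FALSE`) while their prescriptions are costed
normally. All arithmetic is exact integer cents; `ss + remaining = total`
holds to the cent in every row.

The package also ships a seeded synthetic-cohort generator emulating the
marginal structure of the EPI3 cross-sectional survey (group sizes
1691/3187/1501; sector-2 shares 6.9%/4.9%/49.3%; DLD prevalence
29.5%/18.7%; per-tier prescription-size distributions; non-medicinal
prescription rates), and the comparison statistics of that analysis:
descriptive tables, Pearson chi-squared tests, and one-way ANOVA with
pairwise contrasts against the conventional-medicine (CM) reference.

## Worked example

Cost the three-visit example shipped with the package:

```r
library(gpcost)
visits <- read_visits(system.file("extdata", "example_visits.csv", package = "gpcost"))
drugs  <- read_drug_lines(system.file("extdata", "example_druglines.csv", package = "gpcost"),
                          visits = visits)
b <- cost_visits(visits, drugs)
b[, c("visit_id", "sector", "consultation_ss", "consultation_remaining",
      "prescription_ss", "prescription_remaining", "health_expenditure",
      "consultation_costed")]
#>   visit_id sector consultation_ss consultation_remaining prescription_ss
#> 1       V1     S1            14.4                    7.6            8.90
#> 2       V2     S2            22.0                   10.0            5.75
#> 3       V3    NUA             0.0                    0.0            0.00
#>   prescription_remaining health_expenditure consultation_costed
#> 1                  10.10               41.0                TRUE
#> 2                   3.25               41.0                TRUE
#> 3                   0.20                0.2               FALSE
```

V1 is an adult, non-DLD, sector-1 visit: Social Security pays
0.70 x 22 − 1 = 14.40 EUR of the consultation and the patient side keeps
7.60 EUR; its 10 EUR tier-65% box yields 0.65 x 10 − 0.25 = 6.25 EUR to
Social Security. V2 is a DLD child at a sector-2 GP: the full 22 EUR base
is reimbursed (no lump sum under 18) and the 10 EUR sector-2 excess stays
in the remaining cost; its DLD-related line is covered at 100% minus the
franchise. V3 saw a "Not under agreement" GP: the consultation cannot be
costed, only the prescription contributes.

The published headline contrast is recomputed the same way the report
does:

```r
headline_ratio(68.93, 86.63)   # Ho vs CM mean health expenditure, EUR
#> [1] 20.4                     # the published "20 % less expensive"
```

A full synthetic run — generate, cost, compare, write a report bundle:

```r
run_pipeline("report/", cohort = cohort_config(seed = 42))
```

or from a shell via the bundled CLI (exit codes: 0 ok, 2 validation,
3 I/O):

```sh
Rscript $(Rscript -e 'cat(system.file("cli","gpcost.R",package="gpcost"))') \
    pipeline --seed 42 --out-dir report/
```

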