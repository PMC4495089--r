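---
title: "Micro-costing French GP care: model, generator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-costing French GP care: model, generator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcost)
```

## The costing model

`gpcost` implements the rule-based attribution of French general-practice
care costs to three payer perspectives, under the statutory system in force
in 2008: the cost to Social Security (l'Assurance Maladie), the *remaining*
cost (borne by the patient and/or their supplementary insurer — the two
cannot be separated because supplementary contracts differ per patient),
and total health expenditure, the sum of the two. Each perspective is
split into a consultation component and a drug-prescription component,
giving the 3 x 3 grid produced by `cost_visits()` and
`total_management_cost()`.

### Consultation rules

* A sector-1 consultation costs the statutory tariff, 22 EUR; a sector-2
  consultation is modelled at a flat 32 EUR. In both sectors Social
  Security computes its reimbursement on the 22 EUR *contractual base*:
  70% of it normally, 100% for patients with a recognised long-duration
  disease (DLD/ALD). The sector-2 excess (32 − 22 = 10 EUR) is therefore
  never reimbursed and falls entirely in the remaining cost. This is the
  only attribution consistent with a multi-payer system in which sector-2
  physicians set free fees while the statutory insurer reimburses on the
  agreed base.
* Patients aged strictly over 18 pay a 1 EUR per-consultation lump sum
  (*participation forfaitaire*). By default it is netted against the
  Social-Security share (`lump_sum_mode = "net_ss"`), so it surfaces in
  the remaining cost; the model conditions it on age only — DLD adults pay
  it too, since the statutory rule has no DLD exemption. An alternative
  convention, charging it on top of the tariff as a separate patient
  amount (`"add_patient"`), is available because group-level summary
  tables cannot distinguish the two conventions; both conserve
  `ss + remaining = total`.
* Consultations with "Not under agreement" (NUA) physicians — the ~1% of
  GPs outside the statutory contract — are not reimbursed and their free
  fees are unobservable; they cannot be costed. Such visits carry
  `consultation_costed = FALSE`, contribute zero to the consultation
  component, and are excluded from the consultation-cost and total-cost
  denominators in the comparison stage. Their prescriptions are costed
  normally.

### Drug prescription rules

A prescription line costs `unit_price x n_boxes`. Its effective
reimbursement rate is 100% when the line is related to the patient's
long-duration disease (`dld_related`), otherwise the drug's statutory 2008
tier: 0%, 35%, 65% or 100%. The Social-Security amount is the rate times
the line total, minus the 0.25 EUR per-box franchise (the *medical
exemption*, levied only on reimbursed boxes), floored at zero per line —
the floor is applied after netting rate and franchise within a line, never
across lines, so the result is independent of line order. `dld_related` is
a per-line flag, not a per-visit one, because DLD coverage extends only to
care and medicines related to the qualifying pathology.

Two points the statutory texts leave open at this summary level are
exposed as configuration switches rather than hard-coded:
`child_franchise_exempt` (French law exempts minors from the franchise;
the default applies it unconditionally, matching the 2008 accounting
convention the model reproduces) and the lump-sum convention described
above.

### Numerical representation

All money flows through the engine as integer euro-cents. Fractional-cent
intermediates (tier x total) are computed with the rate held as integer
basis points, so the product is an exact integer and half-cent cases round
half-away-from-zero deterministically. Conservation —
`ss + remaining = total` in every row of the grid — therefore holds
cent-exactly, and the vectorized engine (`cost_visits()`) agrees
cent-for-cent with an independent straight-line per-visit/per-line/per-box
reference (`cost_visits_reference()`); the test suite verifies both on
thousands of randomized visits.

## The synthetic cohort

No patient-level data accompany the published EPI3 economic analysis, so
`generate_cohort()` draws a cohort that reproduces its *marginal*
structure: group sizes 1691 (CM) / 3187 (Mx) / 1501 (Ho); sector-2 shares
6.9% / 4.9% / 49.3% and NUA shares 0% / 0.5% / 2%; DLD prevalence 29.5%
(CM) and 18.7% (Ho); per-group, per-tier prescription-line counts; and the
published non-medicinal prescription rates and sick-leave durations
(means 11 / 13 / 12 days).

Choices where no value was published, made once and kept:

* **Mx DLD prevalence** 0.25 — between the published CM and Ho values and
  near the 28% survey-wide DLD figure.
* **Adult share** 0.85 and a two-point child/adult age mixture: the
  costing rules depend on age only through the >18 threshold.
* **Supplementary-insurance shares** 0.94 / 0.95 / 0.96 — about 96% of
  the French population holds supplementary cover, slightly higher in the
  Ho group as reported.
* **Unit prices** log-normal with median 5 EUR and `sdlog` 0.8 — a
  realistic right-skewed price law; no price distribution was published,
  and no costing rule depends on the price law.
* **Boxes per line** `1 + Poisson(0.4)`; **DLD-related line share** 0.5
  among DLD patients' lines; **homeopathic line probabilities**
  0.01 / 0.08 / 0.45, which reproduce the qualitative ordering of the
  homeopathic-only / conventional-only / mixed prescription shares.

Per-tier line counts are drawn as *independent* negative-binomial counts
matched by moments to the per-tier mean and SD (Poisson, with a notice,
where the configured SD implies under-dispersion — as for the
non-reimbursable tier in the CM group); the prescription total is their
sum. The published headline moments of totals (3.1 / 2.8 / 3.5 drugs per
prescription) are retained for reporting but are not a constraint: the
per-tier and headline figures are rounded summaries of the same data and
are not exactly consistent with one another (the Mx per-tier means sum to
2.9), so the generator treats the finer-grained per-tier margins as the
targets. `validate_fidelity()` accordingly z-scores every realized
marginal against its *generator* target at the realized group size and
flags |z| > 4.

**What passing tests do and do not show.** The generator emulates margins
only: all patient attributes are independent draws, so joint structure the
survey never reported (DLD x prescription size, age x sector, severity
gradients) is absent. In particular, with a single price law shared by all
groups, the simulated *prescription* costs do not reproduce the published
cost ordering between groups (the real Ho prescriptions were cheaper per
line, largely because homeopathic medicines are cheap; the generator gives
Ho more lines at the same price law). The structural acceptance checks
therefore target the consultation-cost pattern, which is driven by the
sector mix the generator does reproduce, and treat the published cost
means as external anchors for recomputation, never as quantities the
simulation should match.

## Statistics

The comparison stage mirrors the original analysis plan: quantitative
variables described by group size, mean, SD, median, quartiles, range and
missing count; qualitative variables by counts and percentages computed on
the non-missing sample; chi-squared tests (Pearson, no continuity
correction — the r x c default of SAS, the package used for the original
analysis) for qualitative variables; one-way ANOVA for costs with an
overall F-test p-value and each group contrasted against the CM reference
in a two-group ANOVA (equivalently the pooled-variance t-test, F = t²); 5%
significance threshold; no multiple-testing correction. ANOVA on raw costs
assumes a homoscedastic one-way layout even though cost data are
right-skewed; this mirrors the original means/SD analysis, and the test
suite verifies by simulation (1000 seeded replicates of a null cohort of
3 x 200 visits with identical cost-generating parameters) that the
rejection rate at the 5% level stays within 4–6%.

`headline_ratio()` reports `100 x (mean_b − mean_a) / mean_b`, the
percent by which one strategy undercuts a reference mean — e.g.
`headline_ratio(68.93, 86.63)` = 20.4, the published 20% saving.

## Problem sizes and determinism

Everything is seeded: `generate_cohort()` is byte-identical for a fixed
seed, and `run_pipeline()` writes a manifest (seed, config hashes,
package version) such that a rerun reproduces the bundle byte-for-byte.
The test suite exercises the engine oracle on 1000 randomized visits,
the conservation/monotonicity properties on a 10,000-visit cohort, the
marginal-recovery checks at the full survey scale (6379 visits), and the
ANOVA size calibration on 1000 replicates of 600 visits each; the whole
suite runs in about a minute.

## Known limitations

* Costs excluded upstream remain excluded here: hospital admissions, home
  consultations, and the monetization of sick leave (reported in physical
  units only). The 44% average sector-2 fee overrun is likewise replaced
  by the flat 32 EUR sector-2 tariff of the source costing convention.
* The remaining cost pools patient out-of-pocket and supplementary-insurer
  payments; contract heterogeneity is not modelled.
* The published cost means derive from unavailable patient-level data and
  are not reproducible from the synthetic cohort; only printed-table
  recomputations and structural patterns are checkable.
* Prescription-type percentages in the source exclude an unreported
  phytotherapy/oligotherapy-only stratum from their denominators; the
  generator does not attempt to emulate that stratum.
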