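---
title: "Methods: budget impact of switching oral antipsychotics to aripiprazole-depot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: budget impact of switching oral antipsychotics to aripiprazole-depot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchbia)
```

## The model

switchbia implements a single-cohort, pre-post budget-impact analysis (BIA)
of switching schizophrenia patients from oral antipsychotics (phase A,
months 1–6) to a long-acting injectable, aripiprazole-depot (phase B,
months 7–12), from the perspective of the German statutory health
insurance. Each patient serves as their own control. The analysis chain is

1. **per-patient costing**: utilization quantities × unit costs over 13
   cost categories (one indirect category — productivity losses — and 12
   direct ones);
2. **aggregation**: exact cent-arithmetic sample totals over the cohort
   (n = 132) and per-case means (sample total / n, kept at full precision);
3. **extrapolation**: per-case × prevalent patient count, with the
   prevalent population at 0.8–0.9% of 82 million adults aged 18–65
   (656,000–738,000 patients) and substitution (market-share) scenarios of
   4–12%, plus the hypothetical 100% bound;
4. **one-way sensitivity analysis**: each of seven parameters varied to its
   lower and upper bound while all others are held at base values;
5. **endpoint statistics**: paired Wilcoxon signed-rank tests of phase A
   vs phase B, a one-sided exact binomial test of the phase-B
   hospitalization rate against an external 38.1% reference, and
   sample-size planning with dropout inflation.

Two entry modes feed the chain. **Component-table mode** starts from a
per-case cost table for both arms (the packaged reference table is the
published one); **cohort mode** starts from a patient-level table, either
supplied as CSV or drawn by the calibrated synthetic generator. Both modes
produce the same `component_table` container, so every downstream stage is
agnostic to the source.

The per-case cost table is stored internally as *exact sample totals in
integer cents*. The published sample totals are internally exact (the 13
categories sum to the printed totals to the cent), while the per-case
values are rounded views of sample total / 132; all extrapolations
therefore use the unrounded quotient. This reproduces the published
national totals to within a few euros out of billions (relative error
around 4e-9, far inside the 1e-6 documentation tolerance) — the remaining
discrepancy is consistent with the original computation having carried a
per-case value with a few more rounding digits.

## Unit costs and the productivity rule

Fixed unit rates: 90 €/sick-leave day, 13.37 €/emergency-service contact,
171 €/emergency-physician contact, 515.97 €/depot injection. Day-clinic/PIA
days (120–360 €) and hospital days (90–385 €) have admissible price ranges
rather than single national rates; their base defaults to the range
midpoint and both are overridable — the published per-case table is not
derivable from any single per-diem, which is one reason component-table
mode is the canonical reproduction path.

Productivity losses become relevant to the statutory health insurance from
the sixth week of continuous sick leave (sickness benefit replaces
employer-paid wages after day 42). The applied day-to-cost mapping of the
original analysis is not recoverable: the printed 437.02 € per-case
productivity loss is not consistent with mean sick-leave days of 40.06 over
24 employed patients at 90 €/day under any simple rule. The package
therefore makes the rule explicit: `all_days` (default) prices every
sick-leave day, `sickness_benefit` prices only days beyond the 42nd per
phase.

## One-way sensitivity analysis

Occurrence parameters (sick-leave days, day-clinic days, hospital days,
emergency contacts) are varied between explicit bounds — mean ± SD of the
cost-relevant variable, truncated at zero. The linked cost component is
rescaled by the ratio `varied / base mean`. This ratio rule was adopted
because it reproduces the published productivity-loss and hospital-day
cells to the cent (e.g. oral productivity-loss max:
437.018 × 69.68/40.06 added back onto the base total gives 10,258.50 €;
the truncated hospital-day min removes the entire component, giving
4282.58 €/3269.52 € per arm). The registry stores the *listed* per-arm
bounds rather than recomputing mean ± SD, because one listed bound
(emergency physician, oral arm: min 0.00 with mean 1.42, SD 0.79)
deliberately deviates from the formula.

Two published cell families are **not** reproducible under this — or any
recoverable — rule: the day-clinic occurrence/cost cells and the
emergency-parameter max cells. They are computed under the documented rule
and excluded from reproduction claims. Cost-mode parameters (hospital-day
and day-clinic per-diems) rescale by `varied price / base price`; the
hospital-day base price defaults to the rate implied by the table
(per-case component / mean days, ≈206 €/day oral), the day-clinic base to
the configured rate. Two conflicting day-clinic price ranges circulate
(120–360 € catalogue per-diems vs 240–720 € in the analysis listing); both
ship as named presets, `analysis` being the default.

Parameters are ranked by the induced per-case cost range. On the reference
inputs, hospital-day occurrence ranks first and the two emergency
parameters last, in both arms.

## The synthetic cohort generator

The original patient-level data are not public, so the generator exists to
make every downstream stage testable with data of the right statistical
shape. Its defaults are the study's reported conditions: n = 132, two
183-day phases, employment 24/39/51/9/9
(employed/unemployed/retired/education/unknown), phase-A/phase-B
hospitalization rates 55.1%/14%, mean hospitalizations 0.63/0.16, hospital
days 27.39 (SD 41.37)/5.56 (SD 20.70), day-clinic days 46.13 (SD
45.47)/7.29 (SD 15.02), episodes 2.58 (SD 2.91)/0.41 (SD 0.76),
psychiatrist visits 10.57/7.73, sick-leave days 40.06 (SD 29.62)/15.80
(SD 24.67) in the employed stratum, and mean euro amounts per category
equal to the published per-case values.

Distributional families, chosen to reproduce the zero inflation and
overdispersion implied by SD > mean:

* hospitalization occurrence ~ Bernoulli(rate); hospitalizations given
  occurrence ~ zero-truncated Poisson with the conditional mean
  (unconditional mean / rate);
* day quantities given any use ~ log-normal, moment-matched to the
  conditional mean/SD and censored at the 183-day phase window — the
  log-mean is adjusted (closed-form censored mean, root-finding) so the
  *censored* expectation equals the target, then draws are rounded to whole
  days;
* episodes ~ negative binomial (Poisson when not overdispersed);
  psychiatrist visits ~ Poisson;
* emergency contacts ~ Bernoulli occurrence × zero-truncated Poisson. The
  listed means (e.g. 2.38 service contacts, oral) are consistent with
  means *among patients with any contact*; occurrence rates are recovered
  from per-case cost / unit rate / conditional mean (0.0985 and 0.053 for
  the oral arm);
* euro amounts ~ log-normal with coefficient of variation 1 (a typical
  dispersion for cost data; the source reports no spread for these);
  inpatient fee amounts are drawn only for hospitalized patients;
* depot injections ~ binomial(6, m/6) with m = 2325.57/515.97 ≈ 4.51 —
  at most one injection per month of phase B.

**Cross-phase coupling.** Each patient carries a standard-normal latent
"frailty"; every occurrence channel combines it with fresh noise at weight
`sqrt(frailty_correlation)` (default 0.4) and maps the result through a
Gaussian copula. Marginals — and hence all calibrated moments — are exactly
preserved while frail patients are high utilizers in both phases.
Conditional severities reuse the occurrence channel's uniform rescaled by
the rate (`u/rate` is exactly uniform given occurrence), which keeps the
conditional distribution undistorted at the price of making severity
comonotone with occurrence depth within a channel. Because of heavy tails
and zero inflation, the induced Pearson correlation between phase-A and
phase-B day counts is small though positive; the generator makes no claim
to reproduce a specific empirical correlation (none is reported).

**Choices where the source is silent** (set once, not revisited): any-use
rates for day-clinic days (0.60/0.25 by phase) and sick leave among the
employed (0.70/0.35) — the log-normal conditional-moment construction
requires `rate ≥ mean² / (mean² + var)`, which rules out smaller values for
phase A; money CV 1; default seed 20160501. The sick-leave targets are
taken as unconditional means over the employed stratum. An optional
`missingness` rate (default 0) blanks individual count/day quantities to
emulate item non-response; the true non-response pattern is unreported.

**What passing calibration shows — and does not.** Over 200 replicate
cohorts every calibrated mean and rate recovers its target within
Monte-Carlo error (the package's acceptance checks use 3 MC standard
errors). SDs are matched *before* censoring and integer rounding, so the
realized SD of day quantities sits slightly below target (about 9% for
phase-A hospital days). The generator reproduces moments, not the joint
dependence structure, diagnosis subtypes, adherence mechanisms or side
effects of real patients; passing tests demonstrate the pipeline's
arithmetic and calibration machinery, not clinical validity of simulated
records.

## Endpoint statistics

`compare_paired()` drops zero differences (classical Wilcoxon convention),
uses the exact signed-rank distribution for up to 25 effective pairs
without ties among absolute differences, and the normal approximation with
continuity correction otherwise — the source names the test but not its
tie/approximation policy. Normality screening (Lilliefors-corrected
Kolmogorov-Smirnov, estimated-parameter reference) is attached as advisory
metadata only; the reported test is always the Wilcoxon. The binomial
comparison against the external 38.1% hospitalization rate is the exact
tail probability. Sick-leave endpoints are computed on the employed stratum
only.

Sample-size planning: the one-sample normal approximation for detecting
27.1% vs the 38.1% reference (one-sided α = 0.05, power 0.80) gives
n = 114; an exact-binomial search is also provided. The published n = 116
is not exactly recoverable by either standard method, so the module records
the method used and asserts a bracket, not the printed value. Dropout
inflation is `ceiling(n / (1 - dropout))`, reproducing 116 → 129 at 10%.

## Numerical conventions

* Money is held as integer cents (stored in doubles, exact to 2^53);
  category sums and sample totals are exact; rounding is commercial
  half-up, applied only at presentation.
* Patient counts in scenarios stay fractional (656,000 × 0.04 is used as
  an exact product); the published scenario cells are consistent with
  unrounded products.
* Costs are reported per 6-month phase, as printed; whether an "annual"
  figure doubles them is left to the caller (no annualization flag is
  applied by default).
* Degenerate inputs: all-zero targets produce an all-zero cohort; a zero
  base mean with a nonzero varied value is an error (nothing to rescale);
  all-tied paired samples yield a flagged degenerate result with no
  p-value.
* German-locale rendering (`1.234.567,89 €`) is a formatting flag on
  report output; parsing is its exact inverse.

## Problem sizes

The packaged checks use 200 replicate cohorts of n = 132 for calibration
recovery, full 2^n sign enumeration up to 10 pairs for the signed-rank
oracle, and direct binomial-mass summation up to n = 1000 — all chosen as
comfortably sufficient for 3-SE Monte-Carlo resolution on the quantities
they test.

## Known limitations

* Patient-level costing of synthetic cohorts does not reproduce the
  published component table (the published category means are mutually
  irreconcilable with the published utilization means for productivity
  losses and day-clinic days); component-table mode is the canonical
  reproduction path.
* The day-clinic and emergency sensitivity cells of the source are not
  reproducible under any rule consistent with the reproducible cells.
* The BIA is a single-period comparison: no discounting, no multi-year
  uptake dynamics, no modelling of adverse events or adherence.

## A worked base case

```{r base-case}
ct <- reference_component_table()
round(ct_per_case_total(ct, "oral"), 2)
round(ct_per_case_total(ct, "depot"), 2)
compute_savings(ct, population_scenario(0.008))
head(rank_parameters(one_way_analysis(
  ct, reference_sensitivity_parameters(), list()), "oral"), 3)
```
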