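---
title: "Screening medication effects on the corrected QT interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening medication effects on the corrected QT interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtscreen)
```

## The problem

Prolongation of the heart-rate-corrected QT interval (QTc) predisposes to
Torsades de Pointes and sudden cardiac death, and medications are its most
common cause. Controlled drug studies measure QTc effects in narrow
populations; real-world effects — modulated by demographics, comorbidities
and co-medication — are much harder to observe systematically. `qtscreen`
implements a high-throughput observational screen over routinely collected
data: machine-measured ECG intervals, pharmacy fill records, patient
demographics/comorbidity flags, and a curated torsades-risk class table.
For every drug it contrasts ECGs taken while patients were plausibly
taking the drug against ECGs from the *same patients' population* taken
off the drug, then screens which patient-level factors modify each drug's
effect.

Because the data such screens run on are protected health information, the
package ships a synthetic cohort generator with exported ground truth;
every stage is exercised and calibrated against data whose true effects
are known.

## Pipeline stages

### 1. QTc computation and ECG quality control

The QT interval shortens as heart rate rises, so raw QT values are
corrected before comparison. Five corrections are computed for every ECG
(QT and QTc in ms, RR in s, HR in bpm):

| Formula     | Correction                                   |
|-------------|----------------------------------------------|
| Bazett      | QTc = QT / √RR                               |
| Fridericia  | QTc = QT / RR^(1/3)                          |
| Hodges      | QTc = QT + 1.75 (HR − 60)                    |
| Framingham  | QTc = QT + 154 (1 − RR)                      |
| Rautaharju  | QTc = QT + 18.5 (RR − 1) + 6·[male]          |

All published constants on the seconds scale are rescaled to
milliseconds internally, so at 60 bpm every correction is the identity
(Rautaharju adds its fixed 6 ms sex term for men). Hodges is sometimes
printed without the leading QT term; we implement the standard additive
form above, which is the only form that is dimensionally coherent with
the others. The Rautaharju variant used here is the printed linear form,
not the later rate-ratio forms.

Quality filters (`filter_criteria()`) restrict the analysis set to ECGs
where QTc quantification is reliable: sinus rhythm, outpatient setting,
heart rate 40–100 bpm (inclusive — boundary rates are kept), QRS
< 120 ms (strict, matching the conventional bundle-branch-block cutoff),
and Bazett QTc 300–700 ms (inclusive). The QTc bound is evaluated on the
Bazett value only, because that is the correction conventionally used
for inclusion; the other four corrections are carried through for the
cross-formula analyses. Records with missing or non-positive intervals
are excluded with reason `malformed` and logged — never dropped
silently — and a record violating several criteria is logged once per
reason, so per-criterion exclusion counts are exact.

### 2. Exposure classification

Pharmacy fills become half-open coverage intervals
`[fill_date, fill_date + days_supply)`. Overlapping or abutting
intervals for one (patient, drug) are merged; we deliberately do not
stack overlapping supplies into extended coverage, because refill
behaviour does not reliably indicate stockpiling and merging is the
conservative choice. Medication-list entries that carry no days supply
are bounded at 90 days by default (`ehr_list_days`) before merging.

Each (ECG, drug) pair receives exactly one status:

* `on` — the ECG date lies inside a coverage interval;
* `off_pre` — before the first coverage;
* `off_post` — more than `washout_days` (default 90) past the end of the
  last coverage;
* `indeterminate` — gaps between refills and the 0–90-day post-coverage
  washout, where drug effect may persist;
* `ineligible` — an off-status ECG with no fill of that drug within
  `eligibility_days` (default 365) of the ECG date.

The eligibility rule is the design's confounding control: off-drug ECGs
come only from patients prescribed the drug within a year of the ECG, so
the on and off groups share the indication. Gaps between refills stay
indeterminate rather than off — a patient between fills may well still
be taking the drug. Whether the post-treatment washout clock starts at
the last fill date or when its supply runs out is genuinely ambiguous in
practice; both are supported (`washout_anchor`), and the default anchors
at the coverage end so the clock starts when pills plausibly run out.
The `off_mode = "pre_only"` option restricts off-drug ECGs to
pre-treatment ones, the standard sensitivity analysis for carry-over and
indication drift; `"pooled"` (default) uses both sides.

### 3. Effect estimation

For each drug and each formula the effect is the difference in mean QTc,
on minus off. 95% confidence intervals come from a percentile bootstrap
with 1000 replications: both groups are resampled independently with
replacement, the mean difference is recomputed per replication, and the
2.5th/97.5th percentiles are reported. The percentile method is the
simplest bootstrap consistent with reporting a resampling CI; the
resampling unit defaults to the ECG, with a patient-level cluster option
because patients contribute multiple ECGs (with fewer than two clusters
on a side it falls back to ECG-level with a warning). Each
(drug, formula) pair draws its replicate stream from a child seed hashed
from the drug and formula names, so adding or removing a drug never
perturbs the other drugs' intervals, and screens are exactly
reproducible under a fixed seed.

A heart-rate sensitivity check applies the same estimator to heart rate:
a drug whose apparent QTc effect is an artefact of rate correction will
show a matching heart-rate shift.

Cross-formula consensus (`consensus_top()`): a drug is a consensus
prolonger when it ranks in the top *k* by estimated effect under at
least 3 of the 5 formulas; rank ties break alphabetically and the
consensus list orders by mean rank. The interaction screen runs on this
consensus set by default.

### 4. Interaction screening

For each drug and each covariate we fit, by ordinary least squares,

QTc = a + b·medication + c·covariate + d·medication·covariate

on the drug's on/off cohort, where `medication` is the on-drug
indicator. The interaction coefficient `d` — for a binary covariate, the
difference-in-differences of the four cell means — measures how much the
drug's effect differs across covariate levels. Age enters in decades so
coefficients read per 10 years; race/ethnicity is reduced to a binary
non-White indicator for the screen (full multi-level modelling is out of
scope); comorbidities are 0/1 flags. p-values are normal-theory t tests
from the simple regression, matching the screen's exploratory purpose.
Within each medication the family of covariate tests is Bonferroni
corrected: significant means `p < α / m` with `m` the number of
*estimable* covariate tests for that medication (α = 0.05). Collinear
designs — for example every on-drug ECG sharing one covariate level —
are flagged inestimable with a reason and excluded from both the family
size and the heat map, which reports `d` for significant cells and `NA`
elsewhere.

### 5. Risk-class concordance

Drug-level effects (primary formula) are joined to a user-supplied
torsades-risk class table (drugs absent from the table count as
unclassified) and summarised per class. `ordering_check()` verifies the
screen's qualitative validity: mean estimated prolongation should not
increase as curated risk decreases across
known risk → avoid-in-congenital-LQTS → conditional → possible →
unclassified.

## The synthetic cohort generator

`generator_config()` defaults describe a large outpatient ECG cohort:
age 59.81 (SD 18.67) years, 53.5% female, 44.6% non-White; hypertension
23.1%, coronary artery disease 10.9%, heart failure 7.6%, diabetes
10.3%, chronic kidney disease 8.8%, liver disease 1.5%, COPD 2.7%;
heart rate 73.2 (SD 12.56) bpm truncated to 40–100. Covariate effects on
QTc default to typical univariate values for such a cohort (e.g. +7.2 ms
for female sex, +17.1 ms for heart failure, +2.5 ms per age decade).
The residual noise SD defaults to 27.7 ms: the covariate mix above
contributes roughly √95 ≈ 9.8 ms of between-patient SD, so the marginal
Bazett QTc SD lands near 29.4 ms, and the 412 ms baseline puts the
marginal mean near 437 ms. True QTc is additive in baseline, covariate
effects, the effects and interactions of every drug covered on the ECG
date, and Gaussian noise; heart rate is truncated normal; QT is
back-computed by inverting Bazett (QT = QTc·√RR), so the pipeline's
forward Bazett computation recovers the intended QTc to machine
precision. The other four corrections are therefore internally
consistent but not separately calibrated — cross-formula conclusions
from synthetic data are structural, not numeric.

Prescribing is Bernoulli per (patient, drug) at catalogue prevalences;
an episode is a fill sequence with Poisson short gaps and occasional
long gaps (7% chance, 100–300 days) that exceed the washout, so
post-treatment and indeterminate windows all occur. ECG dates are
sampled before, during and after episodes plus a uniform background. A
configurable contamination fraction receives exactly one filter
violation (non-sinus, inpatient, rate outside 40–100, QRS ≥ 120, or QTc
outside 300–700), and clean records are clamped to pass the default
filters, so the generator's bookkeeping predicts the filter's exclusion
set exactly. An optional confounding-by-indication stressor prescribes a
chosen drug preferentially to patients with high covariate-driven
baseline QTc — useful for demonstrating (not fixing) the bias the
same-population restriction addresses.

What the generator does *not* emulate: correlated comorbidities (flags
are independent; the analysis model is additive and pairwise, so
independence suffices for recovery testing — a correlation hook is the
natural extension point), longitudinal disease progression, dose and
adherence behaviour, electrolyte disturbances, and drug-drug
interactions. Passing tests on synthetic data therefore demonstrate that
the estimators recover what the design assumes, not that the design
deconfounds real EHR data.

## Numerical choices and degenerate inputs

* Dates compare at day resolution; time-of-day is ignored.
* Coverage intervals are half-open; `end` is the first uncovered day.
  The post-treatment boundary `date ≥ end + washout` is equivalent to
  "more than `washout` days after the last covered day".
* Degenerate bootstrap inputs (constant groups) yield a CI equal to the
  point estimate; an empty side makes the drug unreportable rather than
  an error mid-screen.
* Rank ties (drug selection, consensus) break alphabetically so results
  are order-independent.
* The bootstrap restores the caller's RNG state; all internal seeds
  derive from configuration via a 31-bit string hash.
* Generated heart rate is rounded to 0.1 bpm before QT back-computation,
  so stored tables are faithful to what the forward pipeline sees.

## Problem sizes used in the tests

The shipped experiments are sized for precision at desk scale: oracle
equivalence checks run 10,000 randomized exposure instances and 10,000
filtered records; bootstrap coverage uses 200 simulated datasets of 500
ECGs per side (noise SD 25 ms, true effect +15 ms) with 1000
replications each; null calibration uses 20 null drugs and 20 × 10 null
interactions; class-ordering recovery uses stepped class effects of
8/4/2/1/0 ms with four drugs per class and 2000 ECGs per side at noise
SD 10, which puts adjacent class-mean differences several standard
errors apart; end-to-end cohorts use 2000–4000 synthetic patients. The
interaction-recovery experiment raises the study drug and comorbidity
prevalence to 0.3 so its smallest design cell holds a few hundred ECGs.

## Limitations

The screen is exploratory: it estimates associations under a
same-population restriction, not causal effects. Adherence is inferred
from fills; external prescriptions and non-adherence bias estimates
toward zero. The Bonferroni family is per medication (covariates only);
screening many medications still multiplies families. Normal-theory
p-values ignore within-patient correlation — the patient-level bootstrap
option is the provided remedy. Real deployments should treat flagged
drugs and interactions as hypotheses for dedicated confirmation.
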