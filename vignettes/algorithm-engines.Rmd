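---
title: "Methods: rule engines, outcome definitions, trial statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule engines, outcome definitions, trial statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`epoctr` implements two electronic patient-management algorithms for
children aged 2–59 months presenting with acute fever (axillary temperature
≥ 37.5 °C, history ≤ 7 days), the composite outcome definitions used to
compare them, the non-inferiority statistics of that comparison, and a
generative model of a febrile outpatient cohort. This vignette is the
package's own account of the science: the rules, the choices that were
genuinely open, the numerical conventions, and the limits of what the
synthetic cohort can demonstrate.

## 1. The two rule engines

Both engines are pure functions from a validated patient tibble to a
classification-and-management tibble. Severe classifications force referral
(and a pre-referral intramuscular antibiotic); the engines differ in how
they detect severity and in how they decide non-severe antibiotic
treatment.

**e-POCT** evaluates a severe block first: CNS danger signs (severe
lethargy, stiff neck, ≥ 2 convulsions), severe respiratory distress (speech
reduced to single words/grunts, short phrases with lower chest indrawing,
respiratory rate at or above the 97th percentile for age and temperature,
or SaO2 < 90%), severe anaemia (Hb < 60 g/l), severe malnutrition
(weight-for-age z < −3, or MUAC < 115 mm when older than 6 months), severe
dehydration (not tolerating oral liquids with heart rate at or above the
90th percentile), hypoglycaemia (< 3.3 mmol/l, measured only when a
danger/severe branch demands it), and a corneal-clouding/severe-mouth-ulcer
trigger. Any severe classification plus a positive malaria rapid test adds
severe malaria. Non-severe patients then flow through: cough with
tachypnea (≥ 75th percentile) is CRP-gated into bacterial (band ≥ 80 mg/l)
versus viral lower respiratory tract infection; cough without tachypnea is
an upper respiratory infection; a positive malaria test is uncomplicated
malaria; significant diarrhea/vomiting (> 5 loose stools/24 h, ≥ 3 stools
with any emesis, or > 3 emeses) is gastrointestinal disease needing ORS;
skin lesions get subtype-specific care; fever without source (FWS) is
CRP/PCT-gated (bacterial iff CRP ≥ 80 mg/l or PCT ≥ 4 µg/l); and Hb below
the age-banded cutoff (90/100/110 g/l for 2–6/7–24/25–59 months) but ≥ 60
is non-severe anaemia. Day-0 antibiotics go only to severe disease,
bacterial LRTI, bacterial FWS, or a bacterial skin subtype (abscess,
cellulitis, impetigo/pyoderma).

**ALMANACH** is sign-driven: one convulsion is already severe; severe
pneumonia is chest indrawing, cyanosis or stridor; severe anaemia is severe
palmar pallor; severe dehydration is "vomits everything" or 2 of 4 signs;
severe malnutrition is visible severe wasting or bilateral pedal oedema;
jaundice, mastoid swelling, and large/complicated skin lesions (> 4 cm, red
streaks, tender nodes, multiple abscesses) are other severe disease.
Non-severe: cough with a respiratory rate ≥ 50/min regardless of age is
clinical pneumonia (antibiotic); FWS is likely bacterial on purulent ear
discharge, a positive urine dipstick (< 2 years, or dysuria), or a positive
typhoid rapid test (≥ 2 years); all non-severe skin infections receive an
antibiotic. ALMANACH never consumes CRP, PCT, SaO2, Hb or glucose — the
test suite asserts this isolation.

### Staged test ordering

`required_tests_epoct()` returns the next point-of-care test in cascade
order: malaria rapid test, haemoglobin and oximetry for everyone; glucose
when a severe/danger branch demands it; CRP only for tachypneic coughers
and malaria-negative FWS; procalcitonin only for malaria-negative FWS with
CRP below the bacterial band. `required_tests_almanach()` orders dipstick
and typhoid testing by age within FWS. Classification with a missing
demanded test raises a typed incomplete-workup error naming the test —
never a silent default.

### Design choices that were open

- **FWS operationalization.** "Fever without source" has no formal
  definition; we use: no cough, no significant diarrhea/vomiting, no skin
  lesion, not severe, and (for e-POCT) no ear discharge or dysuria. Under
  ALMANACH, ear discharge and dysuria do not exclude FWS because they feed
  its likely-bacterial leg directly. Dysuria alone (any age) triggers a
  dipstick.
- **Severe patients skip the biomarker cascade.** Referral precedes CRP/PCT
  testing in the consultation flow, so severe patients are not routed
  through the CRP/PCT-gated branches; coexisting findings that need no
  further testing (GI, skin lesions, anaemia bands) are still recorded —
  multiple classifications per patient are expected.
- **The corneal-clouding/mouth-ulcer trigger** is wired as `other_severe`.
  Its source criterion also mentions cough with tachypnea; that clause is
  the CRP-gate criterion, not a referral trigger, so it is not wired as
  severe. This label is flagged as uncertain and the rule is data, not
  code: every cutoff resolves through the `reference_standards()` registry.
- **Death within day 7** is not itself a clinical-failure criterion (the
  failure table is symptom-based); deaths surface through the
  severe-adverse-event channel. In the simulator, deaths follow severe
  trajectories, so the accounting stays coherent.
- **Evaluation order** is fixed (severe block → malaria → respiratory → GI
  → skin → FWS) purely for reproducible rule traces; within blocks the
  rules are independent predicates.

## 2. Reference standards: one home for every cutoff

Every threshold lives in `reference_standards()`: haemoglobin 60 g/l
(severe) and 90/100/110 g/l (age-banded anaemia), glucose 3.3 mmol/l, CRP
band `ge80`, PCT 4.0 µg/l, MUAC 115 mm (> 6 months), weight-for-age z −3,
SaO2 90%, skin lesion 4 cm, ALMANACH breathing cutoffs 50 (and 50/40 for
the IMCI-style age-banded rule), follow-up tachypnea cutoffs 60/50, fever
thresholds 37.5 °C (enrollment) and 38.0 °C (day 7), ≥ 3 stools/day
(failure), 3 pp margin, and the convulsion thresholds (2 for e-POCT, 1 for
ALMANACH). Boundary conventions are asserted at the exact values in the
tests: Hb = 60 is *not* severe (strict <), PCT = 4.0 *is* bacterial (≥),
RR = 50 *is* very fast breathing (≥), MUAC = 115 is *not* severe (strict
<), SaO2 = 90 is *not* hypoxemic (strict <).

Two reference objects are approximations by necessity:

- **Respiratory/heart-rate percentile curves.** The age- and
  temperature-corrected percentile curves used clinically are not published
  with the algorithms. The package ships editable tabulated grids (age
  bands 2–11, 12–23, 24–59 months × temperature 37.5–40.5 °C in 0.5 °C
  steps), interpolated piecewise-linearly in temperature and clamped at the
  grid edges, exact at grid nodes, validated monotone non-decreasing in
  temperature. They are stated approximations; substitute published curves
  via `reference_standards(rr97_grid = ...)`.
- **Growth reference.** Weight-for-age z-scores use the LMS transform
  z = ((w/M)^L − 1)/(L·S) against a bundled *synthetic* monthly LMS table
  (`wfa_lms_synthetic.csv`, monotone-spline-expanded from a small set of
  anchor medians, constant L = −0.2 and S ≈ 0.13–0.14). It reproduces the
  shape and scale of an under-five weight-for-age standard but is not the
  WHO 2006 table; replace it via `reference_standards(wfa_reference = ...)`
  for any clinical use. Note the z-score is increasing in weight at fixed
  age and sex; the test suite brute-force-scans this monotonicity and reads
  the −3 SD line back from the bundled table.

## 3. Outcome definitions

Clinical failure by day 7 is a composite: severe disease at any contact
through day 7 (coma, > 2 convulsions/24 h, inability to drink or
breastfeed, SaO2 < 90%, respiratory rate ≥ 97th percentile, heart rate ≥
90th percentile — the *same* registry functions the engines use); clinical
pneumonia (cough history with RR ≥ 60/min under 12 months or ≥ 50/min
otherwise, or with lower chest indrawing) or facility-level dehydration at
the day-3 contact; and, at the day-7 contact, persistent fever (reported or
≥ 38.0 °C), clinical pneumonia, diarrhea ≥ 3 liquid stools/day, significant
dehydration, serious skin infection, or a new significant symptom. Day
windows default to the observed contact ranges (day 3: days 2–5; day 7:
days 6–12) and are configurable. The earliest qualifying day is recorded
with every criterion that fired on it; failure is monotone in added
observations. A patient with no day-7-window contact who is not known dead
is lost to follow-up with failure undefined; `build_populations()` then
counts the lost as failures under ITT and excludes them under PP. "Not
cured" (re-treatment trigger) is caregiver-reported illness or any fever ≥
37.5 °C. Severe adverse events by day 30 are deaths, else secondary
admissions — hospitalizations after day 0, so a day-0 primary-referral
admission does not count.

## 4. Trial statistics: conventions

- **Risk ratio:** Katz log-method CI,
  exp(log RR ± z·√(1/a − 1/n_a + 1/b − 1/n_b)). **Risk difference:** Wald
  CI in percentage points. **Chi-squared:** Pearson without continuity
  correction. These conventions were chosen to match classical epi-table
  procedures and are verified in the tests against hand-evaluated formulas
  and published table values; they are inferences, since the original
  analyses do not name their CI methods. Two rounding artefacts are
  documented rather than forced: the primary-outcome risk difference is
  −1.77 pp unrounded (prints as −1.7 under round-half-toward-zero
  conventions), and the referral-vs-routine risk ratio is 17.836 (prints as
  17.83) while its CI (4.42, 72.02) matches the Katz computation exactly.
- **Zero cells:** no automatic 0.5 correction; `zero_correction = TRUE` is
  an explicit opt-in, and a zero-event comparator arm is otherwise an
  error.
- **Non-inferiority:** declared iff the upper bound of the two-sided 95% CI
  of the risk difference is *strictly* below the margin (3 pp default); a
  bound exactly on the margin is inconclusive.
- **Mantel–Haenszel RR:** MH weights with the Greenland–Robins variance and
  a Cochran-style heterogeneity statistic; reduces to the crude RR for one
  stratum; cross-checked against an independent published implementation
  (`metafor::rma.mh`) in the tests.
- **Kaplan–Meier** uses `survival::survfit`; the wrapper adds a queryable
  step function and tidy/autoplot methods; tested against a hand-computed
  10-subject product-limit table.
- **Sample size:** per-arm ⌈(z₁₋α + z_power)²(p_a q_a + p_b q_b)/margin²⌉.
  At p = 0.10 both arms, margin 3 pp, 80% power, one-sided α = 0.025 this
  gives 1,570/arm (3,140 total), and the design-point simulation below
  recovers ≈ 80% empirical power — the two are internally consistent.

## 5. The synthetic cohort

`generate_cohort()` draws latent conditions from a configurable etiology
mixture (defaults: viral URTI 24%, viral LRTI 22%, gastroenteritis 13%,
FWS-viral 18%, malaria 11%, skin conditions 4.5%, severe malnutrition 3%,
plus small bacterial and severe-anaemia fractions), ages from banded
weights (44/33/23% for 2–11/12–23/24–59 months), and then vitals and
staged POCT results conditioned on the condition: malaria is mRDT-positive
at 97% sensitivity (1% false positive), bacterial conditions draw elevated
CRP bands (60% ≥ 80 mg/l) and log-normal PCT centred near 6 µg/l, the
severe-anaemia state draws Hb ~ N(52, 6) g/l, respiratory conditions add
respiratory-rate offsets, and weight is drawn through the inverse LMS
transform from z ~ N(−0.8, 1.1) (the severe-malnutrition state uses
N(−3.6, 0.35)). Clinician-judgment signs get deliberately poor sensitivity
(severe palmar pallor detects 25% of true severe anaemia; visible severe
wasting 2% of severe malnutrition) — this is the mechanism by which the
sign-driven comparator under-refers.

Randomness follows a one-root-seed, per-patient-substream contract:
patient i's draws depend only on (seed, i), so enlarging a cohort extends
it without reshuffling — a property the tests assert byte-identically.

`simulate_followup()` links management to outcome through an explicit
appropriateness computation: each condition's required care (antibiotic,
antimalarial, referral, supportive token) lives in `condition_care_map()`;
each missing component multiplies the condition's base failure probability
(defaults: ×3 missing antibiotic/antimalarial, ×4 missing referral, ×2
missing supportive care, ×1.3 unnecessary antibiotic). Failures manifest as
trajectory features the outcome engine actually detects (day-3 pneumonia
signs, day-7 persistent fever or diarrhea, unscheduled severe events);
severe adverse events and deaths attach mostly to failures; loss to
follow-up removes the day-7 window contact at a configured rate (default
0.4%). The multipliers and base failure probabilities are an *illustrative
calibration* chosen once so that the simulated per-protocol failure
proportions land near the published arm-level marginals (≈ 2% vs ≈ 4%);
they are configuration, not estimated truth, and only the *sign* of the
arm contrast is asserted in tests.

**Design-point mode.** With `failure_probability_override` set, clinical
failure is iid Bernoulli(p) regardless of condition and management. Under
that override, each arm's failure count in a simulated trial is exactly
Binomial(n, p), so the 1,000-replicate power study
(`simulate_design_point_trials()`) draws the binomial counts directly
instead of pushing 3.1 million synthetic patients through the engines —
an exact marginalization, not an approximation. The equivalence is itself
exercised by the parameter-recovery check, which runs the full generate →
classify → follow-up → assess pipeline under the same override at n = 5,000
and recovers the configured probability within binomial standard error
(pooled over four fixed seeds, since a single-seed one-SE band is by
construction only a ~68% event).

**What passing tests do and do not show.** The simulator emulates the
*structure* of a febrile outpatient cohort — mixture etiologies,
condition-conditioned biomarkers, management-dependent outcomes — not its
full epidemiology: no seasonality, no co-infections (beyond severe
malaria's definition), no HIV/malnutrition interaction, no care-seeking
behaviour, and conditional independence of signs given the condition where
real signs correlate. Green tests therefore demonstrate that the engines,
outcome definitions and statistics are implemented faithfully and hang
together; they do not validate the algorithms' clinical performance on
real children.

## 6. Problem sizes and numerical conventions in the test suite

The engine-versus-oracle equivalence runs on an exhaustive discretized
lattice of 186,624 presentations (with a 20,736-point lattice in the unit
tests), spanning the decision surface including the exact boundary values.
Stochastic checks use 1,000 design-point trials at 1,570/arm, 2,000
simulated 2×2 tables at n = 500/arm for Katz coverage (tolerance ±1.5 pp
around 95%), four 5,000-patient pipeline runs for parameter recovery, and
2,500–3,140-patient simulated trials for the arm-contrast sign. Percentile
lookups clamp temperature outside 37.5–40.5 °C; ages outside 2–59 months
are range errors; ties at grid nodes return the tabulated value exactly.
All tolerances in the tests are stated next to the assertion they govern.

## 7. Known limitations

- The growth reference and percentile grids are synthetic/approximate (see
  §2); classifications that hinge on them (severe malnutrition, severe
  tachypnea/tachycardia) are faithful to the rule structure, not to the
  exact published curves.
- Treatment mapping below the antibiotic/referral level (dosing, route,
  duration) is out of scope; treatments are tokens.
- The outcome engine treats "new significant symptom" as a recorded
  assessor judgment, not a derived quantity.
- The mixed-effects adjusted analysis of the original trial design is out
  of scope (standard model-fitting, not algorithm logic).
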