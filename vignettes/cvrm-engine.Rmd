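---
title: "The cvrmdash engine: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cvrmdash engine: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrmdash)
```

cvrmdash is a headless decision-support engine for cardiovascular risk
management (CVRM): it turns raw EHR-style extraction streams into a typed
risk profile, assigns each patient to a 10-year cardiovascular risk model
through declarative business rules, evaluates the risk, flags risk factors
against guideline targets, proposes treatments, and quantifies the benefit
of adhering to them. This vignette explains the science the engine
implements, the parameters that matter, and the design choices we made
where the problem was genuinely open.

## The risk model and its assumptions

Published 10-year cardiovascular risk scores — primary-prevention scores,
the SMART recurrent-event score, the ADVANCE diabetes score, scores for
the elderly — share one functional form, the Cox proportional-hazards
risk equation:

$$\mathrm{risk}(10) = 1 - S_0(10)^{\exp(\mathrm{LP} - \overline{\mathrm{LP}})}$$

where the linear predictor $\mathrm{LP} = \sum_j \beta_j\, x_j$ is a
weighted sum of transformed risk-factor values, $\overline{\mathrm{LP}}$
is its population mean, and $S_0(10)$ is the 10-year event-free
probability of the reference profile. cvrmdash implements exactly this
form, and nothing else: model definitions are *data* (YAML/JSON), each
carrying its predictors, transform tags, coefficients, baseline survival
and citation. The transform vocabulary — `identity`, `log`, `centered`,
`indicator` — covers the published forms of the cited score family;
smoking enters models through a binary current-smoker indicator derived
from the three-level status (current/former/never).

Assumptions inherited from this form: proportional hazards over the
10-year horizon, no competing-risk adjustment (the Elderly slot runs on
the same engine with its own definition), and multiplicative independence
of hazard-ratio interventions (see below).

**The shipped coefficients are illustrative.** The four definitions in
`extdata/models.yaml` have plausible signs and magnitudes so the engine is
runnable and testable end to end, but they are not the published
coefficients; each definition's `citation` field names the source a
deployer must substitute authoritative values from. Because definitions
are configuration, that substitution needs no code change — and the
registry accepts any additional score (e.g. lifetime-horizon scores) under
a new id.

## Business-rule triage

Model choice is a declarative decision tree over the *triage fields* age,
prior CVD and diabetes, evaluated in priority order with the first match
winning:

| priority | condition              | model       |
|---------:|------------------------|-------------|
| 1        | age ≥ 70               | elderly     |
| 2        | prior CVD              | smart       |
| 3        | diabetes               | advance     |
| 4        | (catch-all)            | heart_score |

Two choices here were open and are ours: the *precedence* between
overlapping categories (a 75-year-old with prior CVD triages to the
Elderly score, an 80-year-old diabetic likewise), and the *inclusive*
age-70 boundary. Both live in `extdata/rules.yaml`, so a deployment that
prefers SMART over Elderly for septuagenarians edits one line of config.
`validate_rule_set()` enumerates the full triage-field grid (age bucketed
at the rule thresholds × CVD × diabetes), reports the winner for every
combination, and flags uncovered combinations and unreachable rules; the
shipped set covers all 8 combinations with no unreachable rule.

Triage fields are **never imputed**: which score applies must rest on
observed data. A profile missing a triage field produces a dashboard
payload with an explicit failure section — profile still shown, risk
omitted — rather than an error, because a risk score computed under a
guessed comorbidity status would be silently wrong in the most
consequential way.

## Profile assembly

Four streams mirror the EHR extraction queries: questionnaire
information, measurements, laboratory results and the medication
register. For each risk factor the engine selects the most recent entry
at or before the index date within a look-back window. The window
defaults to 365 days — the dashboard describes the patient *at the
visit*, and a year is the longest interval at which routine risk-factor
measurements are plausibly current — and is configurable per call. Ties
at identical timestamps resolve by stream rank (labs over measurements
over questionnaire), on the argument that the laboratory value is the
instrument-verified one. Prior-CVD events are history and therefore
exempt from the window; an explicit prior-CVD answer wins, but recorded
events imply the flag when the answer is absent.

Units normalize to canonical ones (mmHg; mmol/L with mg/dL accepted at
0.02586; eGFR in mL/min/1.73 m²; HbA1c in IFCC mmol/mol with DCCT %
accepted; hsCRP mg/L; urine protein g/L with mg/dL accepted) through a
config table; an unknown unit is an error, never a guess.

Active prescriptions group by ATC-like class prefix into four therapeutic
classes, each attached beneath its governing risk factor — lipid-lowering
under LDL, blood-pressure-lowering under SBP, glucose-lowering under
HbA1c, antithrombotics under the prior-CVD flag — which is also what
drives the initiate-versus-intensify distinction in suggestions.

## Targets, flags and suggestions

Treatment targets are config (`extdata/targets.yaml`), with illustrative
defaults: SBP < 140 mmHg for every model, LDL < 2.6 mmol/L for primary
prevention and < 1.8 mmol/L for established CVD, HbA1c < 53 mmol/mol for
the diabetes model. The boundary convention is documented and tested:
"below T" means value < T is green, value ≥ T is red. Factors without a
value flag `unknown`, and each red factor yields exactly one suggestion;
a current smoker always receives a lifestyle cessation suggestion in
addition. Pharmacological suggestions carry an evidence link and an
`already_treated` flag (an active drug of the governing class turns
"initiate" into "intensify"). There is no dosing logic by design.

## Counterfactual benefit

The "risk with or without the proposed treatment" view supports two
mechanisms, because which one a deployed dashboard should use is a
genuine modelling choice:

* **`substitute_target`** (default): each toggled intervention sets its
  factor to the target value and the risk is recomputed — the literal
  reading of "if treatment goals are adhered to". Smoking cessation sets
  the status to `former`.
* **`hazard_ratio`**: the scenario survival is
  $S_0^{\exp(\mathrm{LP}-\overline{\mathrm{LP}})\cdot\prod_k \mathrm{HR}_k}$,
  the standard proportional-hazards composition of per-intervention trial
  hazard ratios. Independence of simultaneous interventions is an
  explicit simplification.

Results report absolute risk reduction (baseline − scenario) and relative
reduction (undefined — `NA`, not 0 — when the baseline risk is 0).
Scenario application never mutates the input profile and is idempotent.

## Missing data, imputation and quality metrics

Mean imputation fills a missing model predictor with the per-field mean
of a training cohort, recording provenance `imputed`; observed values are
never overwritten, and every risk estimate and payload lists its imputed
fields so the clinician knows what was estimated. The known bias is
checked analytically in the tests: a fully imputed patient under a
centered model scores exactly $1 - S_0$, the population average.

Two audit metrics follow the validation design of dashboard deployments:
**completeness** is the proportion of *observed* required fields — imputed
values deliberately do not count, since the metric asks what the EHR
provided, so it is identical before and after imputation; the payload
reports post-imputation availability as a separate number. **Accuracy**
is the share of dashboard-presented values agreeing with the raw source
values; the default tolerance is exact for integer-valued pairs and
1e-9 relative otherwise (no clinically meaningful discrepancy survives
either), with per-field absolute overrides available. An empty
comparison is flagged undefined rather than scored 0.

## The synthetic cohort generator

Because the engine must be testable without patient data, the package
generates raw four-stream records for synthetic patients: demographics,
smoking and history in the questionnaire stream; SBP in measurements;
lipids, eGFR, HbA1c, hsCRP and urine protein in labs; class-coded
prescriptions (conditioned on the drawn profile) in the medication
register. Defaults are illustrative mid-range clinic values — e.g.
SBP ~ Normal(135, 18) truncated to [80, 250] mmHg, diabetes prevalence
0.20, prior CVD 0.30, hsCRP and urine protein log-normal — chosen to
exercise every code path including all four model slots. Per-field
missingness is independent Bernoulli, defaulting to 0 for triage fields
and demographics, 0.05 for common labs, and 0.4 for hsCRP and urine
protein, the score-specific analytes most often not ordered in routine
care. Risk-factor correlations are off by default (a simplicity choice;
`cohort_spec()` documents every knob). Generation is deterministic given
the seed and round-trips bytewise through the stream writers.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: free-text fields, values recorded in
unexpected EHR locations, informative (non-random) missingness,
intra-patient longitudinal drift, and unit heterogeneity within one
hospital. Those are exactly the failure modes a deployment validation
against a real EHR copy must cover.

## Numerical and degenerate-input choices

* Baseline survival is validated strictly inside (0, 1); a finite LP then
  keeps risk strictly inside (0, 1) up to floating-point saturation.
* `log` transforms reject non-positive values; positive-valued fields are
  validated strictly positive at assembly.
* Duplicate (patient, code, timestamp) entries are tolerated when the
  values agree and are an integrity error when they conflict.
* Config fingerprints are MD5 over canonical JSON, so a payload records
  exactly which models/rules/targets produced it.
* Payload JSON serialization is canonicalized (serialize–parse–serialize),
  making payload → JSON → payload round-trips bytewise stable.

## Problem sizes used in the checks

The property suite runs 1,000 randomized model/profile pairs against a
direct closed-form oracle (agreement to 1e-12), 10,000 monotonicity
cases, exhaustive 8-combination triage enumeration, and a 1,000-patient
end-to-end fuzz with ~13% triage-field missingness in which every payload
must validate and degraded payloads must actually occur. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

Shipped coefficients and targets are illustrative placeholders (by
design, see above); no competing-risk handling for the elderly slot; mean
imputation only (no regression or multiple imputation); no drug–drug
interaction or contraindication logic; the decision tree assumes one
guideline at a time. The registry and config surfaces are built so none
of these require changes to the engine itself.
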