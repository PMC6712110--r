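# cvrmdash

A headless, testable decision-support engine for **cardiovascular risk
management (CVRM)**. It implements the computational core of a clinical
CVRM dashboard — the part that turns raw EHR extraction streams into a
risk profile, a 10-year cardiovascular risk estimate, guideline
treatment advice and a "what if the patient adheres" projection — as an
R package with a JSON payload contract, so any front end (EHR viewer,
web app, script) can consume it.

It is written for clinical-informatics teams building or validating
CVRM decision support, and for methodologists who need a reproducible
sandbox for risk-score triage, counterfactual benefit and
missing-data behaviour.

## What it computes

Every risk model is a declarative **Cox-form risk equation**

```
risk(10) = 1 − S0(10) ^ exp(LP − LP̄),   LP = Σ βj · xj
```

with per-predictor transforms (`identity`, `log`, `centered`,
`indicator`), baseline survival `S0(10)` and mean linear predictor `LP̄`
shipped as YAML config, not code. Four model slots are registered by
default, matching the business-rule decision tree that assigns each
patient exactly one score:

| subpopulation                      | model slot    |
|------------------------------------|---------------|
| age ≥ 70                           | `elderly`     |
| prior cardiovascular event         | `smart`       |
| diabetes, no prior CVD             | `advance`     |
| otherwise (primary prevention)     | `heart_score` |

The shipped coefficients and treatment targets are **clearly labelled
illustrative values**; each definition carries a `citation` field naming
the published source a deployer substitutes authoritative numbers from
(config only, no code change).

Around that core the package provides: four-stream EHR-style ingestion
(CSV and JSON dialects) with unit normalization and provenance tracking;
red/green flagging against configurable guideline targets; treatment
suggestions (initiate vs intensify, based on active medication classes);
counterfactual risk under on/off intervention toggles (target
substitution or hazard-ratio composition); mean imputation with
imputed-field disclosure; completeness/accuracy data-quality audits; a
seeded synthetic cohort generator; and print / copy-to-consult text
renderings.

## Worked example

```r
library(cvrmdash)

spec     <- cohort_spec(n_patients = 5, seed = 42)
records  <- generate_cohort(spec)
profiles <- lapply(records, assemble_profile, index_date = spec$index_date)
imp      <- fit_imputation_model(profiles)

payload <- build_dashboard(records[[1]], spec$index_date,
                           imputation_model = imp,
                           scenarios = list(scenario()))
cat(render_print(payload), sep = "\n")
```

```
CVRM dashboard — patient P0001 — index date 2024-06-01
------------------------------------------------------------
RISK FACTORS
  age                          81 years
  sex                          female
  smoking                      former
  sbp                          146 mmHg [HIGH]
  total_cholesterol            5.64 mmol/L
  hdl                          - (missing)
  ldl                          4.51 mmol/L [HIGH]
  egfr                         73 mL/min/1.73m2
  diabetes                     no
  hba1c                        52 mmol/mol
  prior_cvd                    no
  family_history_premature_cvd no
  hscrp                        1.94 mg/L
  urine_protein                0.213 g/L

RISK SCORE
  elderly: 22.3% 10-year cardiovascular risk

TREATMENT SUGGESTIONS
  initiate sbp_control [pharmacological]: sbp 146 mmHg -> target 140 mmHg
  initiate ldl_lowering_primary [pharmacological]: ldl 4.51 mmol/L -> target 2.6 mmol/L
```

Reading this: the patient is 81, so the business rules assign the
`elderly` slot; SBP and LDL violate their (illustrative) targets and are
flagged `[HIGH]` with one suggestion each; HDL was missing in the source
streams, which is harmless here because the elderly definition does not
need it (a missing *needed* predictor would be mean-imputed and
disclosed in `payload$risk$fields_imputed`). Toggling a suggestion on
recomputes the risk at the achieved target:

```r
cf <- build_dashboard(records[[1]], spec$index_date, imputation_model = imp,
                      scenarios = list(scenario("sbp_control")))$counterfactuals[[1]]
round(100 * c(baseline = cf$baseline_risk, scenario = cf$scenario_risk,
              ARR = cf$absolute_risk_reduction), 1)
#> baseline scenario      ARR
#>     22.3     21.6      0.7
```

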