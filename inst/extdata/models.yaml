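# Shipped 10-year risk-model definitions for the four business-rule slots.
#
# ILLUSTRATIVE COEFFICIENTS: the numeric values below (coefficients,
# centering references, mean linear predictors, baseline survivals) are
# placeholders with plausible sign and magnitude, shipped so the engine is
# runnable end to end. They are NOT the published score coefficients.
# Deployers must substitute authoritative values from the sources named in
# each `citation` field; definitions are data, so no code change is needed.
heart_score:
  horizon: 10
  baseline_survival: 0.95
  mean_linear_predictor: 0.25
  citation: "illustrative values; substitute coefficients from the Dutch CVRM guideline primary-prevention (SCORE-based) risk table"
  predictors:
    - {field: age, transform: centered, reference: 60, coefficient: 0.071}
    - {field: sex, transform: indicator, level: male, coefficient: 0.37}
    - {field: smoking, transform: indicator, level: current, coefficient: 0.55}
    - {field: sbp, transform: centered, reference: 140, coefficient: 0.012}
    - {field: total_cholesterol, transform: centered, reference: 5.5, coefficient: 0.16}
    - {field: hdl, transform: centered, reference: 1.3, coefficient: -0.42}
smart:
  horizon: 10
  baseline_survival: 0.81
  mean_linear_predictor: 0.45
  citation: "illustrative values; substitute coefficients from the published SMART recurrent-event risk score"
  predictors:
    - {field: age, transform: centered, reference: 60, coefficient: 0.08}
    - {field: sex, transform: indicator, level: male, coefficient: 0.17}
    - {field: smoking, transform: indicator, level: current, coefficient: 0.45}
    - {field: sbp, transform: centered, reference: 140, coefficient: 0.008}
    - {field: ldl, transform: centered, reference: 2.5, coefficient: 0.24}
    - {field: egfr, transform: centered, reference: 75, coefficient: -0.015}
    - {field: hscrp, transform: log, coefficient: 0.25}
    - {field: diabetes, transform: indicator, coefficient: 0.40}
advance:
  horizon: 10
  baseline_survival: 0.88
  mean_linear_predictor: 0.30
  citation: "illustrative values; substitute coefficients from the published ADVANCE cardiovascular risk equation"
  predictors:
    - {field: age, transform: centered, reference: 62, coefficient: 0.06}
    - {field: sex, transform: indicator, level: male, coefficient: 0.25}
    - {field: smoking, transform: indicator, level: current, coefficient: 0.35}
    - {field: sbp, transform: centered, reference: 145, coefficient: 0.010}
    - {field: hba1c, transform: centered, reference: 53, coefficient: 0.030}
    - {field: urine_protein, transform: log, coefficient: 0.35}
    - {field: total_cholesterol, transform: centered, reference: 5.2, coefficient: 0.14}
elderly:
  horizon: 10
  baseline_survival: 0.78
  mean_linear_predictor: 0.35
  citation: "illustrative values; substitute coefficients from the published Elderly (70+) cardiovascular risk score"
  predictors:
    - {field: age, transform: centered, reference: 75, coefficient: 0.07}
    - {field: sex, transform: indicator, level: male, coefficient: 0.30}
    - {field: smoking, transform: indicator, level: current, coefficient: 0.40}
    - {field: sbp, transform: centered, reference: 150, coefficient: 0.006}
    - {field: total_cholesterol, transform: centered, reference: 5.0, coefficient: 0.10}
    - {field: diabetes, transform: indicator, coefficient: 0.45}
    - {field: egfr, transform: centered, reference: 65, coefficient: -0.012}
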