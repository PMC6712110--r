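# Shipped treatment targets.
#
# ILLUSTRATIVE THRESHOLDS in canonical units, shipped so the engine runs
# end to end; deployers must substitute authoritative values from the CVRM
# guideline named in each evidence_link. Boundary convention for "below":
# value < threshold is green, value >= threshold is red.
- factor: sbp
  threshold: 140
  direction: below
  applicable_model_ids: [heart_score, smart, advance, elderly]
  intervention_id: sbp_control
  kind: pharmacological
  drug_class: blood_pressure_lowering
  evidence_link: "https://example.org/cvrm-guideline#blood-pressure"
- factor: ldl
  threshold: 2.6
  direction: below
  applicable_model_ids: [heart_score, advance, elderly]
  intervention_id: ldl_lowering_primary
  kind: pharmacological
  drug_class: lipid_lowering
  evidence_link: "https://example.org/cvrm-guideline#lipids-primary"
- factor: ldl
  threshold: 1.8
  direction: below
  applicable_model_ids: [smart]
  intervention_id: ldl_lowering_secondary
  kind: pharmacological
  drug_class: lipid_lowering
  evidence_link: "https://example.org/cvrm-guideline#lipids-secondary"
- factor: hba1c
  threshold: 53
  direction: below
  applicable_model_ids: [advance]
  intervention_id: glycaemic_control
  kind: pharmacological
  drug_class: glucose_lowering
  evidence_link: "https://example.org/cvrm-guideline#glycaemia"
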