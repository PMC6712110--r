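# Unit-normalization table: canonical unit per field plus accepted input
# units with affine conversion (canonical = scale * value + offset).
# Cholesterol mg/dL -> mmol/L uses 0.02586; HbA1c DCCT % -> IFCC mmol/mol
# uses 10.929 * (% - 2.15); urine protein mg/dL -> g/L uses 0.01.
age:
  canonical: years
  accepted:
    years: {scale: 1.0, offset: 0.0}
sbp:
  canonical: mmHg
  accepted:
    mmHg: {scale: 1.0, offset: 0.0}
total_cholesterol:
  canonical: mmol/L
  accepted:
    mmol/L: {scale: 1.0, offset: 0.0}
    mg/dL: {scale: 0.02586, offset: 0.0}
hdl:
  canonical: mmol/L
  accepted:
    mmol/L: {scale: 1.0, offset: 0.0}
    mg/dL: {scale: 0.02586, offset: 0.0}
ldl:
  canonical: mmol/L
  accepted:
    mmol/L: {scale: 1.0, offset: 0.0}
    mg/dL: {scale: 0.02586, offset: 0.0}
egfr:
  canonical: mL/min/1.73m2
  accepted:
    mL/min/1.73m2: {scale: 1.0, offset: 0.0}
hba1c:
  canonical: mmol/mol
  accepted:
    mmol/mol: {scale: 1.0, offset: 0.0}
    "%": {scale: 10.929, offset: -23.49735}
hscrp:
  canonical: mg/L
  accepted:
    mg/L: {scale: 1.0, offset: 0.0}
urine_protein:
  canonical: g/L
  accepted:
    g/L: {scale: 1.0, offset: 0.0}
    mg/dL: {scale: 0.01, offset: 0.0}
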