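# Business-rule decision tree: first matching rule by priority wins.
# Default precedence: Elderly (age >= 70, inclusive) > SMART (prior CVD)
# > ADVANCE (diabetes; no-prior-CVD is implied by SMART outranking it)
# > heart_score catch-all (primary prevention).
- priority: 1
  predicate: {min_age: 70}
  model_id: elderly
- priority: 2
  predicate: {prior_cvd: true}
  model_id: smart
- priority: 3
  predicate: {diabetes: true}
  model_id: advance
- priority: 4
  predicate: {}
  model_id: heart_score
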