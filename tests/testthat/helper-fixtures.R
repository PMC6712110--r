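# Shared fixtures, all built in code at test time.

# A profile with sensible mid-range values; override any field.
make_profile <- function(..., provenance = "observed") {
  defaults <- list(
    age = 55, sex = "male", smoking = "never", sbp = 130,
    total_cholesterol = 5.0, hdl = 1.4, ldl = 2.4, egfr = 80,
    diabetes = FALSE, hba1c = 40, prior_cvd = FALSE,
    family_history_premature_cvd = FALSE, hscrp = 2.0, urine_protein = 0.1
  )
  overrides <- list(...)
  values <- modifyList(defaults, overrides)
  values <- values[!vapply(values, is.null, TRUE)]
  profile_from_values(values, patient_id = "T001",
                      index_date = as.Date("2024-06-01"),
                      provenance = provenance)
}

# A two-predictor model with hand-checkable arithmetic.
make_simple_model <- function(baseline_survival = 0.95,
                              mean_linear_predictor = 0,
                              coefficients = c(age = 0.05, sbp = 0.01),
                              references = c(age = 60, sbp = 140)) {
  risk_model(
    model_id = "simple",
    predictors = lapply(names(coefficients), function(f) {
      list(field = f, transform = "centered",
           coefficient = coefficients[[f]], reference = references[[f]])
    }),
    baseline_survival = baseline_survival,
    mean_linear_predictor = mean_linear_predictor
  )
}

# Write a four-stream dialect-a fixture directory; `rows` is a named list
# of data frames overriding individual streams.
write_fixture_streams <- function(dir, questionnaire = NULL,
                                  measurements = NULL, labs = NULL,
                                  medications = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  empty <- list(
    questionnaire = "patient_id,item_code,value,timestamp",
    measurements = "patient_id,measure_code,value,unit,timestamp",
    labs = "patient_id,analyte_code,value,unit,timestamp",
    medications = "patient_id,class_code,drug_name,start_date,active"
  )
  streams <- list(questionnaire = questionnaire,
                  measurements = measurements, labs = labs,
                  medications = medications)
  for (s in names(empty)) {
    path <- file.path(dir, paste0(s, ".csv"))
    if (is.null(streams[[s]])) {
      writeLines(empty[[s]], path)
    } else {
      writeLines(c(empty[[s]], streams[[s]]), path)
    }
  }
  dir
}

# A complete two-patient fixture: one primary-prevention smoker with high
# LDL on no medication, one elderly diabetic with prior CVD on a statin.
write_two_patient_fixture <- function(dir) {
  write_fixture_streams(
    dir,
    questionnaire = c(
      'A,age,52,2024-05-01',
      'A,sex,male,2024-05-01',
      'A,smoking,current,2024-05-01',
      'A,diabetes,false,2024-05-01',
      'A,prior_cvd,false,2024-05-01',
      'A,family_history_premature_cvd,true,2024-05-01',
      'B,age,78,2024-04-01',
      'B,sex,female,2024-04-01',
      'B,smoking,never,2024-04-01',
      'B,diabetes,true,2024-04-01',
      'B,prior_cvd,true,2024-04-01',
      'B,prior_cvd_event,myocardial infarction,2020-01-15',
      'B,family_history_premature_cvd,false,2024-04-01'
    ),
    measurements = c(
      'A,sbp,152,mmHg,2024-05-01',
      'B,sbp,138,mmHg,2024-04-01'
    ),
    labs = c(
      'A,total_cholesterol,6.1,mmol/L,2024-05-01',
      'A,hdl,1.1,mmol/L,2024-05-01',
      'A,ldl,4.2,mmol/L,2024-05-01',
      'A,egfr,88,mL/min/1.73m2,2024-05-01',
      'A,hba1c,39,mmol/mol,2024-05-01',
      'B,total_cholesterol,4.8,mmol/L,2024-04-01',
      'B,hdl,1.5,mmol/L,2024-04-01',
      'B,ldl,2.2,mmol/L,2024-04-01',
      'B,egfr,58,mL/min/1.73m2,2024-04-01',
      'B,hba1c,57,mmol/mol,2024-04-01',
      'B,hscrp,3.1,mg/L,2024-04-01',
      'B,urine_protein,0.2,g/L,2024-04-01'
    ),
    medications = c(
      'B,C10AA,atorvastatin,2021-03-01,true',
      'B,A10BA,metformin,2019-06-01,true',
      'B,B01AC,clopidogrel,2020-02-01,false'
    )
  )
}

INDEX <- as.Date("2024-06-01")

# Stable textual serialization of a profile for equality checks.
serialize_profile_chr <- function(p) {
  as.character(jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

# Independent closed-form evaluation of the Cox-form risk used as an
# oracle against the engine (kept free of engine internals).
oracle_risk <- function(s0, lp, lp_bar) 1 - s0 ^ exp(lp - lp_bar)
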