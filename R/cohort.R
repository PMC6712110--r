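# Synthetic cohort generator: UCC-like patients as raw four-stream
# records, with configurable per-field missingness and seeded determinism,
# so every module is testable without any download. Default distribution
# parameters are illustrative — they exercise code paths, they do not
# claim epidemiological realism.

#' Specify a synthetic cohort
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer RNG seed; generation is deterministic given the
#'   seed.
#' @param index_date Visit date profiles are anchored to.
#' @param age_range Uniform age range in years.
#' @param p_male,p_smoking_current,p_smoking_former,p_diabetes,p_prior_cvd,p_family_history
#'   Prevalences in \[0, 1\].
#' @param sbp_mean,sbp_sd Systolic blood pressure Normal(mean, sd), mmHg,
#'   truncated to \[80, 250\].
#' @param tc_mean,tc_sd Total cholesterol Normal, mmol/L, truncated to
#'   \[2, 12\].
#' @param hdl_mean,hdl_sd HDL Normal, mmol/L, truncated to \[0.5, 3\].
#' @param ldl_mean,ldl_sd LDL Normal, mmol/L, truncated to \[0.5, 8\].
#' @param egfr_mean,egfr_sd eGFR Normal, mL/min/1.73m2, truncated to
#'   \[10, 130\].
#' @param hba1c_mean,hba1c_sd HbA1c Normal, mmol/mol (diabetics are drawn
#'   around `hba1c_dm_mean`), truncated to \[20, 130\].
#' @param hba1c_dm_mean HbA1c mean for diabetics.
#' @param hscrp_meanlog,hscrp_sdlog hsCRP log-normal parameters, mg/L.
#' @param up_meanlog,up_sdlog Urine protein log-normal parameters, g/L.
#' @param missingness Named numeric vector field -> probability that the
#'   field is absent from the raw streams. Defaults emulate routine-care
#'   gaps: 0 for demographics/triage fields, 0.05 for common measurements
#'   and labs, 0.4 for hsCRP and urine protein (the score-specific labs
#'   most often not ordered).
#' @param error_injection_rate Probability of corrupting a dashboard-vs-raw
#'   value pair in [generate_validation_pair()].
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100,
                        seed = 1,
                        index_date = as.Date("2024-06-01"),
                        age_range = c(40, 85),
                        p_male = 0.5,
                        p_smoking_current = 0.25,
                        p_smoking_former = 0.35,
                        p_diabetes = 0.20,
                        p_prior_cvd = 0.30,
                        p_family_history = 0.25,
                        sbp_mean = 135, sbp_sd = 18,
                        tc_mean = 5.2, tc_sd = 1.1,
                        hdl_mean = 1.3, hdl_sd = 0.35,
                        ldl_mean = 3.0, ldl_sd = 1.0,
                        egfr_mean = 75, egfr_sd = 18,
                        hba1c_mean = 40, hba1c_sd = 6,
                        hba1c_dm_mean = 55,
                        hscrp_meanlog = 0.7, hscrp_sdlog = 0.6,
                        up_meanlog = -2.2, up_sdlog = 0.5,
                        missingness = NULL,
                        error_injection_rate = 0) {
  default_missing <- setNames(rep(0, length(RISK_FACTOR_FIELDS)),
                              RISK_FACTOR_FIELDS)
  default_missing[c("sbp", "total_cholesterol", "hdl", "ldl", "egfr",
                    "hba1c")] <- 0.05
  default_missing[c("hscrp", "urine_protein")] <- 0.4
  if (!is.null(missingness)) {
    bad <- setdiff(names(missingness), RISK_FACTOR_FIELDS)
    if (length(bad)) {
      config_error(sprintf("missingness names unknown field(s): %s",
                           paste(bad, collapse = ", ")))
    }
    default_missing[names(missingness)] <- missingness
  }
  spec <- list(
    n_patients = n_patients, seed = as.integer(seed),
    index_date = as.Date(index_date), age_range = age_range,
    p_male = p_male, p_smoking_current = p_smoking_current,
    p_smoking_former = p_smoking_former, p_diabetes = p_diabetes,
    p_prior_cvd = p_prior_cvd, p_family_history = p_family_history,
    sbp_mean = sbp_mean, sbp_sd = sbp_sd, tc_mean = tc_mean, tc_sd = tc_sd,
    hdl_mean = hdl_mean, hdl_sd = hdl_sd, ldl_mean = ldl_mean,
    ldl_sd = ldl_sd, egfr_mean = egfr_mean, egfr_sd = egfr_sd,
    hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
    hba1c_dm_mean = hba1c_dm_mean,
    hscrp_meanlog = hscrp_meanlog, hscrp_sdlog = hscrp_sdlog,
    up_meanlog = up_meanlog, up_sdlog = up_sdlog,
    missingness = default_missing,
    error_injection_rate = error_injection_rate
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n_patients) || spec$n_patients < 1) {
    config_error("n_patients must be >= 1")
  }
  probs <- c(spec$p_male, spec$p_smoking_current, spec$p_smoking_former,
             spec$p_diabetes, spec$p_prior_cvd, spec$p_family_history,
             spec$missingness, spec$error_injection_rate)
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    config_error("probabilities must lie in [0, 1]")
  }
  if (spec$p_smoking_current + spec$p_smoking_former > 1) {
    config_error("smoking prevalences must sum to <= 1")
  }
  sds <- c(spec$sbp_sd, spec$tc_sd, spec$hdl_sd, spec$ldl_sd, spec$egfr_sd,
           spec$hba1c_sd, spec$hscrp_sdlog, spec$up_sdlog)
  if (any(!is.finite(sds) | sds <= 0)) {
    config_error("distribution SDs must be > 0")
  }
  invisible(spec)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort as raw four-stream records
#'
#' Draws each patient's risk factors from the spec distributions and
#' writes them into the stream each variable belongs to (labs: lipids,
#' eGFR, HbA1c, hsCRP, urine protein; measurements: SBP; questionnaire:
#' demographics, smoking, history; medication register: class-coded
#' prescriptions conditioned on the drawn profile). Per-field missingness
#' is applied independently. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Named list of [patient_record()]s.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    lapply(setNames(nm = sprintf("P%04d", seq_len(spec$n_patients))),
           function(id) generate_patient(id, spec))
  })
}

generate_patient <- function(id, spec) {
  idx <- spec$index_date
  entry_date <- function() idx - sample.int(300L, 1L)
  miss <- function(field) runif(1) < spec$missingness[[field]]

  age <- round(runif(1, spec$age_range[1], spec$age_range[2]))
  male <- runif(1) < spec$p_male
  smoke_u <- runif(1)
  smoking <- if (smoke_u < spec$p_smoking_current) "current"
             else if (smoke_u < spec$p_smoking_current +
                        spec$p_smoking_former) "former" else "never"
  diabetes <- runif(1) < spec$p_diabetes
  prior_cvd <- runif(1) < spec$p_prior_cvd
  famhist <- runif(1) < spec$p_family_history

  sbp <- round(rnorm_trunc(1, spec$sbp_mean, spec$sbp_sd, 80, 250))
  tc <- round(rnorm_trunc(1, spec$tc_mean, spec$tc_sd, 2, 12), 2)
  hdl <- round(rnorm_trunc(1, spec$hdl_mean, spec$hdl_sd, 0.5, 3), 2)
  ldl <- round(rnorm_trunc(1, spec$ldl_mean, spec$ldl_sd, 0.5, 8), 2)
  egfr <- round(rnorm_trunc(1, spec$egfr_mean, spec$egfr_sd, 10, 130))
  hba1c <- round(rnorm_trunc(
    1, if (diabetes) spec$hba1c_dm_mean else spec$hba1c_mean,
    spec$hba1c_sd, 20, 130))
  hscrp <- round(rlnorm(1, spec$hscrp_meanlog, spec$hscrp_sdlog), 2)
  up <- round(rlnorm(1, spec$up_meanlog, spec$up_sdlog), 3)

  q_code <- character(); q_val <- character()
  add_q <- function(code, value) {
    q_code <<- c(q_code, code)
    q_val <<- c(q_val, as.character(value))
  }
  if (!miss("age")) add_q("age", age)
  if (!miss("sex")) add_q("sex", if (male) "male" else "female")
  if (!miss("smoking")) add_q("smoking", smoking)
  if (!miss("diabetes")) add_q("diabetes", tolower(diabetes))
  if (!miss("prior_cvd")) {
    add_q("prior_cvd", tolower(prior_cvd))
    if (prior_cvd) {
      add_q("prior_cvd_event",
            sample(c("myocardial infarction", "ischaemic stroke",
                     "peripheral artery disease"), 1L))
    }
  }
  if (!miss("family_history_premature_cvd")) {
    add_q("family_history_premature_cvd", tolower(famhist))
  }
  questionnaire <- data.frame(
    item_code = q_code, value = q_val,
    timestamp = idx - sample.int(300L, length(q_code), replace = TRUE),
    stringsAsFactors = FALSE)

  measurements <- if (!miss("sbp")) {
    data.frame(measure_code = "sbp", value = sbp, unit = "mmHg",
               timestamp = entry_date(), stringsAsFactors = FALSE)
  } else empty_measurements()[, 1:4]

  lab_value <- c(total_cholesterol = tc, hdl = hdl, ldl = ldl, egfr = egfr,
                 hba1c = hba1c, hscrp = hscrp, urine_protein = up)
  lab_unit <- c(total_cholesterol = "mmol/L", hdl = "mmol/L",
                ldl = "mmol/L", egfr = "mL/min/1.73m2",
                hba1c = "mmol/mol", hscrp = "mg/L", urine_protein = "g/L")
  keep <- names(lab_value)[!vapply(names(lab_value), miss, TRUE)]
  labs <- data.frame(
    analyte_code = keep, value = unname(lab_value[keep]),
    unit = unname(lab_unit[keep]),
    timestamp = idx - sample.int(300L, length(keep), replace = TRUE),
    stringsAsFactors = FALSE)

  med_code <- character(); med_drug <- character()
  add_med <- function(class_code, drug) {
    med_code <<- c(med_code, class_code)
    med_drug <<- c(med_drug, drug)
  }
  if (prior_cvd) {
    if (runif(1) < 0.7) add_med("C10AA", "simvastatin")
    if (runif(1) < 0.8) add_med("B01AC", "acetylsalicylic acid")
  }
  if (sbp > 140 && runif(1) < 0.5) add_med("C09AA", "enalapril")
  if (diabetes && runif(1) < 0.8) add_med("A10BA", "metformin")
  medications <- data.frame(
    class_code = med_code, drug_name = med_drug,
    start_date = idx - sample.int(1000L, length(med_code), replace = TRUE),
    active = rep(TRUE, length(med_code)), stringsAsFactors = FALSE)

  patient_record(id, questionnaire, measurements, labs, medications)
}

#' Generate a dashboard-vs-raw validation pair with injected discrepancies
#'
#' Builds the raw value map from the observed numeric fields of the
#' assembled cohort profiles (keys `"<patient>:<field>"`), copies it as
#' the dashboard map, and corrupts each pair independently with
#' probability `spec$error_injection_rate` (adding an offset well beyond
#' any agreement tolerance). Deterministic given the spec seed; the
#' ground-truth list of injected keys is returned for assertion.
#'
#' @param spec A [cohort_spec()] with `error_injection_rate` set.
#' @return List: `raw` (named numeric), `dashboard` (named numeric),
#'   `injected` (character keys actually corrupted).
#' @export
generate_validation_pair <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- generate_cohort(spec)
  profiles <- lapply(records, assemble_profile, index_date = spec$index_date)
  raw <- unlist(lapply(profiles, function(p) {
    obs <- NUMERIC_FIELDS[p$provenance[NUMERIC_FIELDS] == "observed"]
    setNames(as.numeric(p$fields[obs]),
             paste(p$patient_id, obs, sep = ":"))
  }))
  with_seed(spec$seed + 1L, {
    corrupt <- runif(length(raw)) < spec$error_injection_rate
    dashboard <- raw
    dashboard[corrupt] <- raw[corrupt] + runif(sum(corrupt), 0.5, 2)
    list(raw = raw, dashboard = dashboard, injected = names(raw)[corrupt])
  })
}
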