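# PatientRecord: raw timestamped entries from the four EHR-style streams
# for one patient (questionnaire, measurements, labs, medication register).

empty_questionnaire <- function() {
  data.frame(item_code = character(), value = character(),
             timestamp = as.Date(character()), recognized = logical(),
             stringsAsFactors = FALSE)
}

empty_measurements <- function() {
  data.frame(measure_code = character(), value = numeric(),
             unit = character(), timestamp = as.Date(character()),
             recognized = logical(), stringsAsFactors = FALSE)
}

empty_labs <- function() {
  data.frame(analyte_code = character(), value = numeric(),
             unit = character(), timestamp = as.Date(character()),
             recognized = logical(), stringsAsFactors = FALSE)
}

empty_medications <- function() {
  data.frame(class_code = character(), drug_name = character(),
             start_date = as.Date(character()), active = logical(),
             stringsAsFactors = FALSE)
}

KNOWN_QUESTIONNAIRE_CODES <- c(
  "age", "sex", "smoking", "diabetes", "prior_cvd", "prior_cvd_event",
  "family_history_premature_cvd"
)
KNOWN_MEASUREMENT_CODES <- c("sbp")
KNOWN_LAB_CODES <- c(
  "total_cholesterol", "hdl", "ldl", "egfr", "hba1c", "hscrp",
  "urine_protein"
)

#' Construct a patient record
#'
#' A `patient_record` holds the raw timestamped entries of one patient in
#' the four EHR-style streams: questionnaire information, measurements,
#' laboratory results and the medication register. Any stream may be empty.
#'
#' @param patient_id Non-empty identifier string.
#' @param questionnaire Data frame with columns `item_code`, `value`,
#'   `timestamp` (Date).
#' @param measurements Data frame with columns `measure_code`, `value`
#'   (numeric), `unit`, `timestamp` (Date).
#' @param labs Data frame with columns `analyte_code`, `value` (numeric),
#'   `unit`, `timestamp` (Date).
#' @param medications Data frame with columns `class_code`, `drug_name`,
#'   `start_date` (Date), `active` (logical).
#' @return A `patient_record` object.
#' @export
patient_record <- function(patient_id,
                           questionnaire = empty_questionnaire(),
                           measurements = empty_measurements(),
                           labs = empty_labs(),
                           medications = empty_medications()) {
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      is.na(patient_id) || !nzchar(patient_id)) {
    integrity_error("patient_id must be a non-empty string")
  }
  questionnaire <- flag_recognized(questionnaire, "item_code",
                                   KNOWN_QUESTIONNAIRE_CODES)
  measurements <- flag_recognized(measurements, "measure_code",
                                  KNOWN_MEASUREMENT_CODES)
  labs <- flag_recognized(labs, "analyte_code", KNOWN_LAB_CODES)
  for (nm in c("questionnaire", "measurements", "labs")) {
    df <- get(nm)
    if (nrow(df) && anyNA(df$timestamp)) {
      format_error(sprintf("unparseable timestamp in %s stream for patient %s",
                           nm, patient_id))
    }
  }
  structure(
    list(patient_id = patient_id,
         questionnaire = order_stream(questionnaire, "timestamp"),
         measurements = order_stream(measurements, "timestamp"),
         labs = order_stream(labs, "timestamp"),
         medications = order_stream(medications, "start_date")),
    class = "patient_record"
  )
}

flag_recognized <- function(df, code_col, known) {
  if (nrow(df)) {
    df$recognized <- df[[code_col]] %in% known
  } else if (!"recognized" %in% names(df)) {
    df$recognized <- logical(0)
  }
  df
}

order_stream <- function(df, time_col) {
  if (!nrow(df)) return(df)
  df <- df[order(df[[time_col]], seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$patient_id, "\n")
  cat(sprintf("  questionnaire: %d  measurements: %d  labs: %d  medications: %d\n",
              nrow(x$questionnaire), nrow(x$measurements), nrow(x$labs),
              nrow(x$medications)))
  invisible(x)
}

#' Is an object a patient record?
#' @param x Object.
#' @return Logical.
#' @export
is_patient_record <- function(x) inherits(x, "patient_record")
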