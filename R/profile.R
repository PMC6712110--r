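# RiskProfile: the merged, typed cardiovascular risk-factor set with
# per-field provenance (observed / imputed / missing).

#' Construct an empty risk profile
#'
#' @param patient_id Identifier string.
#' @param index_date Date the profile is anchored to.
#' @return A `risk_profile` with every risk factor missing.
#' @export
risk_profile <- function(patient_id, index_date) {
  fields <- setNames(vector("list", length(RISK_FACTOR_FIELDS)),
                     RISK_FACTOR_FIELDS)
  structure(
    list(
      patient_id = patient_id,
      index_date = as.Date(index_date),
      fields = fields,
      prior_cvd_events = character(),
      medications_by_class = list(),
      provenance = setNames(rep("missing", length(RISK_FACTOR_FIELDS)),
                            RISK_FACTOR_FIELDS)
    ),
    class = "risk_profile"
  )
}

#' Construct a risk profile directly from values
#'
#' Convenience constructor for programmatic use (scenario exploration,
#' simulation, testing): fields listed in `values` are set with the given
#' provenance; everything else stays missing.
#'
#' @param values Named list of field values (names from
#'   [risk_factor_fields()]).
#' @param patient_id Identifier string.
#' @param index_date Date the profile is anchored to.
#' @param provenance Provenance to record for the supplied values
#'   (`"observed"` or `"imputed"`), either a single value or a named
#'   vector per field.
#' @return A `risk_profile`.
#' @export
profile_from_values <- function(values, patient_id = "anon",
                                index_date = Sys.Date(),
                                provenance = "observed") {
  bad <- setdiff(names(values), RISK_FACTOR_FIELDS)
  if (length(bad)) {
    schema_error(sprintf("unknown profile field(s): %s",
                         paste(bad, collapse = ", ")))
  }
  if (length(provenance) == 1L) {
    provenance <- setNames(rep(provenance, length(values)), names(values))
  }
  profile <- risk_profile(patient_id, index_date)
  for (f in names(values)) {
    profile <- set_field(profile, f, values[[f]], provenance[[f]])
  }
  profile
}

#' Get a risk-factor value from a profile
#'
#' @param profile A `risk_profile`.
#' @param field Field name.
#' @return The value, or `NULL` when provenance is missing.
#' @export
profile_value <- function(profile, field) {
  profile$fields[[field]]
}

profile_has <- function(profile, field) {
  profile$provenance[[field]] %in% c("observed", "imputed")
}

set_field <- function(profile, field, value, provenance) {
  validate_field_value(field, value)
  profile$fields[[field]] <- value
  profile$provenance[[field]] <- provenance
  profile
}

validate_field_value <- function(field, value) {
  if (field %in% NUMERIC_FIELDS) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
      integrity_error(sprintf("field '%s' must be a finite number", field))
    }
    if (field == "age" && value < 0) {
      integrity_error("age must be >= 0")
    }
    if (field %in% POSITIVE_FIELDS && value <= 0) {
      integrity_error(sprintf("field '%s' must be strictly positive", field))
    }
  } else if (field %in% LOGICAL_FIELDS) {
    if (!is.logical(value) || length(value) != 1L || is.na(value)) {
      integrity_error(sprintf("field '%s' must be TRUE/FALSE", field))
    }
  } else if (field == "sex") {
    if (!value %in% SEX_LEVELS) {
      integrity_error(sprintf("sex must be one of: %s",
                              paste(SEX_LEVELS, collapse = ", ")))
    }
  } else if (field == "smoking") {
    if (!value %in% SMOKING_LEVELS) {
      integrity_error(sprintf("smoking must be one of: %s",
                              paste(SMOKING_LEVELS, collapse = ", ")))
    }
  }
  invisible(value)
}

# Candidate raw entries for one field: rows from every stream the field can
# live in, normalized to (value, unit, timestamp, stream).
field_candidates <- function(record, field) {
  sources <- FIELD_SOURCES[[field]]
  rows <- lapply(sources, function(src) {
    stream <- src[[1]]
    code <- src[[2]]
    df <- record[[stream]]
    code_col <- switch(stream, questionnaire = "item_code",
                       measurements = "measure_code", labs = "analyte_code")
    df <- df[df[[code_col]] == code, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    data.frame(
      value = as.character(df$value),
      unit = if ("unit" %in% names(df)) as.character(df$unit) else NA_character_,
      timestamp = df$timestamp,
      stream = stream,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Assemble a risk profile from a patient record
#'
#' For every risk factor the most recent eligible entry is selected: the
#' entry with the latest timestamp at or before `index_date` and no older
#' than `recency_window` days. Fields with no eligible entry are marked
#' `missing`. Entries tied on timestamp are resolved by stream rank
#' (labs > measurements > questionnaire). Numeric values are normalized to
#' canonical units; an unknown unit is an error, never a guess.
#'
#' An explicit `prior_cvd` questionnaire answer wins; when only
#' `prior_cvd_event` entries exist, `prior_cvd` derives TRUE from them.
#'
#' @param record A [patient_record()].
#' @param index_date Date the dashboard is rendered for (the visit date).
#' @param recency_window Look-back window in days (> 0, default 365).
#' @param units A `unit_table` for normalization.
#' @return A `risk_profile` with provenance `observed` or `missing` per
#'   field.
#' @export
assemble_profile <- function(record, index_date, recency_window = 365,
                             units = default_unit_table()) {
  stopifnot(is_patient_record(record))
  index_date <- as.Date(index_date)
  if (!is.finite(recency_window) || recency_window <= 0) {
    config_error("recency_window must be > 0")
  }
  profile <- risk_profile(record$patient_id, index_date)

  for (field in RISK_FACTOR_FIELDS) {
    cand <- field_candidates(record, field)
    if (is.null(cand) || !nrow(cand)) next
    age_days <- as.numeric(index_date - cand$timestamp)
    cand <- cand[age_days >= 0 & age_days <= recency_window, , drop = FALSE]
    if (!nrow(cand)) next
    cand$rank <- STREAM_RANK[cand$stream]
    cand <- cand[order(cand$timestamp, cand$rank), , drop = FALSE]
    chosen <- cand[nrow(cand), ]
    value <- coerce_field_value(field, chosen$value, chosen$unit, units)
    profile <- set_field(profile, field, value, "observed")
  }

  # Event list: all prior CVD events recorded at or before the index date
  # (history does not expire with the recency window).
  q <- record$questionnaire
  ev <- q[q$item_code == "prior_cvd_event" & q$timestamp <= index_date, ,
          drop = FALSE]
  profile$prior_cvd_events <- unique(as.character(ev$value))
  if (length(profile$prior_cvd_events) &&
      !profile_has(profile, "prior_cvd")) {
    profile <- set_field(profile, "prior_cvd", TRUE, "observed")
  }
  profile
}

coerce_field_value <- function(field, raw, unit, units) {
  if (field %in% NUMERIC_FIELDS) {
    num <- suppressWarnings(as.numeric(raw))
    if (is.na(num)) {
      format_error(sprintf("non-numeric value '%s' for field '%s'",
                           raw, field))
    }
    convert_unit(field, num, unit, units)
  } else if (field %in% LOGICAL_FIELDS) {
    val <- parse_logical_value(raw)
    if (is.na(val)) {
      format_error(sprintf("non-boolean value '%s' for field '%s'",
                           raw, field))
    }
    val
  } else {
    tolower(trimws(as.character(raw)))
  }
}

#' Attach active medications grouped by therapeutic class
#'
#' Active prescriptions are grouped into the four therapeutic classes
#' (lipid-lowering, blood-pressure-lowering, glucose-lowering,
#' antithrombotic) by their ATC-like class-code prefix, so each drug can be
#' displayed beneath its governing risk factor (e.g. a statin beneath the
#' LDL value). Inactive prescriptions are excluded. Unrecognized class
#' codes raise a warning and are grouped under `"other"`.
#'
#' @param profile A `risk_profile`.
#' @param record The [patient_record()] the profile came from.
#' @return The profile with `medications_by_class` populated (named list of
#'   drug-name character vectors).
#' @export
attach_medication_classes <- function(profile, record) {
  stopifnot(inherits(profile, "risk_profile"), is_patient_record(record))
  meds <- record$medications
  meds <- meds[!is.na(meds$active) & meds$active, , drop = FALSE]
  by_class <- list()
  for (i in seq_len(nrow(meds))) {
    cls <- classify_medication(meds$class_code[i])
    if (cls == "other") {
      warning(sprintf("unrecognized medication class code '%s' (%s); grouped under 'other'",
                      meds$class_code[i], meds$drug_name[i]),
              call. = FALSE)
    }
    by_class[[cls]] <- c(by_class[[cls]], meds$drug_name[i])
  }
  profile$medications_by_class <- lapply(by_class, unique)
  profile
}

classify_medication <- function(code) {
  code <- toupper(trimws(code))
  for (cls in names(MED_CLASS_PREFIXES)) {
    for (p in MED_CLASS_PREFIXES[[cls]]) {
      if (startsWith(code, p)) return(cls)
    }
  }
  "other"
}

#' Does the profile carry an active medication of a therapeutic class?
#'
#' @param profile A `risk_profile` with medications attached.
#' @param class_name One of `lipid_lowering`, `blood_pressure_lowering`,
#'   `glucose_lowering`, `antithrombotic`, `other`.
#' @return Logical.
#' @export
has_medication_class <- function(profile, class_name) {
  length(profile$medications_by_class[[class_name]]) > 0L
}

#' Binary current-smoker indicator
#'
#' Smoking is stored three-valued (current/former/never); risk models
#' consume the binary indicator derived here.
#'
#' @param profile A `risk_profile`.
#' @return TRUE/FALSE, or NA when smoking is missing.
#' @export
is_current_smoker <- function(profile) {
  if (!profile_has(profile, "smoking")) return(NA)
  identical(profile$fields$smoking, "current")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile>", x$patient_id, "  index date:",
      format(x$index_date), "\n")
  for (f in RISK_FACTOR_FIELDS) {
    v <- x$fields[[f]]
    cat(sprintf("  %-28s %-10s %s\n", f,
                if (is.null(v)) "-" else format(v),
                x$provenance[[f]]))
  }
  if (length(x$medications_by_class)) {
    cat("  medications:\n")
    for (cls in names(x$medications_by_class)) {
      cat(sprintf("    %s: %s\n", cls,
                  paste(x$medications_by_class[[cls]], collapse = ", ")))
    }
  }
  invisible(x)
}

# Stable serialization used by determinism and immutability checks.
serialize_profile <- function(profile) {
  jsonlite::toJSON(unclass(profile), auto_unbox = TRUE, digits = NA,
                   null = "null")
}
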