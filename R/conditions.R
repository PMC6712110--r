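# Classed error conditions so callers can react to specific failure modes
# (format vs integrity vs missing data) instead of matching message text.

cvrm_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "cvrm_error", "error")))
}

format_error <- function(message, ...) {
  cvrm_abort("cvrm_format_error", message, ...)
}

integrity_error <- function(message, ...) {
  cvrm_abort("cvrm_integrity_error", message, ...)
}

unit_error <- function(field, unit) {
  cvrm_abort(
    "cvrm_unit_error",
    sprintf("cannot convert unit '%s' for field '%s'", unit, field),
    field = field, unit = unit
  )
}

missing_data_error <- function(fields) {
  cvrm_abort(
    "cvrm_missing_data_error",
    sprintf("required fields missing: %s", paste(fields, collapse = ", ")),
    fields = fields
  )
}

missing_triage_field_error <- function(fields) {
  cvrm_abort(
    c("cvrm_missing_triage_field_error", "cvrm_missing_data_error"),
    sprintf("triage fields missing (never imputed): %s",
            paste(fields, collapse = ", ")),
    fields = fields
  )
}

triage_error <- function(message) {
  cvrm_abort("cvrm_triage_error", message)
}

schema_error <- function(message, ...) {
  cvrm_abort("cvrm_schema_error", message, ...)
}

registration_error <- function(message) {
  cvrm_abort("cvrm_registration_error", message)
}

scenario_error <- function(message, ...) {
  cvrm_abort("cvrm_scenario_error", message, ...)
}

config_error <- function(message) {
  cvrm_abort("cvrm_config_error", message)
}
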