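# Dashboard payload assembly: orchestrates assemble -> triage -> impute ->
# score -> flag -> suggest -> counterfactual into one structured payload,
# degrading gracefully (a failure section, never a crash) when patient
# data, rather than configuration, is the problem.

#' Fingerprint a configuration object
#'
#' MD5 of the canonical JSON serialization; changes iff the configuration
#' content changes.
#'
#' @param x Any serializable configuration object (registry, rules,
#'   targets, imputation model).
#' @return Length-1 character MD5 hex digest.
#' @export
config_fingerprint <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Build the complete dashboard payload for one patient
#'
#' Runs the full pipeline: profile assembly, medication attachment,
#' business-rule triage, mean imputation of the selected model's
#' predictors, risk evaluation, red/green target flagging, treatment
#' suggestions, counterfactual scenarios and the data-quality report.
#' Patient-level data problems (missing triage fields, unfillable
#' predictors) are reported inside the payload's `failures` section with
#' the profile still shown; only configuration errors abort.
#'
#' @param record A [patient_record()].
#' @param index_date Visit date.
#' @param registry A `model_registry` (default: shipped four-slot
#'   registry).
#' @param rules A `triage_rules` set (default: shipped rules).
#' @param targets A `treatment_targets` list (default: shipped targets).
#' @param imputation_model Optional [fit_imputation_model()] result; when
#'   `NULL` no imputation is attempted.
#' @param scenarios List of [scenario()]s to evaluate counterfactually.
#' @param recency_window Profile look-back window in days.
#' @return A `dashboard_payload`.
#' @export
build_dashboard <- function(record, index_date,
                            registry = default_model_registry(),
                            rules = default_triage_rules(),
                            targets = default_targets(),
                            imputation_model = NULL,
                            scenarios = list(),
                            recency_window = 365) {
  profile <- assemble_profile(record, index_date, recency_window)
  profile <- attach_medication_classes(profile, record)

  failures <- list()
  model_id <- NULL
  estimate <- NULL
  statuses <- NULL
  suggestions <- list()
  counterfactuals <- list()

  model_id <- tryCatch(
    select_model(profile, rules),
    cvrm_missing_triage_field_error = function(e) {
      failures$triage <<- list(message = conditionMessage(e),
                               missing_fields = e$fields)
      NULL
    },
    cvrm_triage_error = function(e) {
      failures$triage <<- list(message = conditionMessage(e),
                               missing_fields = character())
      NULL
    }
  )

  if (!is.null(model_id)) {
    definition <- get_model(registry, model_id)
    if (!is.null(imputation_model)) {
      profile <- impute(profile, imputation_model,
                        definition$required_fields)
      unfilled <- attr(profile, "unfilled")
      attr(profile, "unfilled") <- NULL
    } else {
      unfilled <- definition$required_fields[
        !vapply(definition$required_fields, profile_has, TRUE,
                profile = profile)]
    }
    statuses <- evaluate_targets(profile, model_id, targets)
    suggestions <- suggest_treatments(profile, statuses, targets, model_id)
    estimate <- tryCatch(
      ten_year_risk(profile, definition),
      cvrm_missing_data_error = function(e) {
        failures$risk <<- list(message = conditionMessage(e),
                               missing_fields = e$fields)
        NULL
      }
    )
    if (!is.null(estimate)) {
      # a scenario whose toggles do not apply to this patient is a
      # patient-level issue, reported in the payload, not a crash
      skipped <- list()
      counterfactuals <- lapply(scenarios, function(scen) {
        tryCatch(counterfactual_risk(profile, scen, definition, suggestions),
                 cvrm_scenario_error = function(e) {
                   skipped[[length(skipped) + 1L]] <<-
                     list(message = conditionMessage(e),
                          toggles = scen$toggles)
                   NULL
                 })
      })
      counterfactuals <- Filter(Negate(is.null), counterfactuals)
      if (length(skipped)) failures$scenarios <- skipped
    }
  }

  required <- unique(c(
    intersect(triage_fields(),
              unlist(lapply(rules, function(r) predicate_fields(r$predicate)))),
    if (!is.null(model_id)) get_model(registry, model_id)$required_fields
    else risk_factor_fields()
  ))
  quality <- list(
    completeness = completeness(profile, required),
    post_imputation_availability = mean(
      profile$provenance[required] %in% c("observed", "imputed")),
    required_fields = required,
    per_field_status = as.list(profile$provenance[required])
  )

  structure(
    list(
      patient_id = record$patient_id,
      index_date = as.character(as.Date(index_date)),
      profile = list(
        fields = profile$fields,
        provenance = as.list(profile$provenance),
        prior_cvd_events = profile$prior_cvd_events,
        medications_by_class = profile$medications_by_class
      ),
      statuses = as.list(statuses),
      selected_model_id = model_id,
      risk = if (is.null(estimate)) NULL else unclass(estimate),
      suggestions = lapply(suggestions, unclass),
      counterfactuals = lapply(counterfactuals, function(cf) {
        cf <- unclass(cf)
        cf$scenario <- unclass(cf$scenario)
        cf
      }),
      quality = quality,
      failures = failures,
      engine_version = as.character(packageVersion("cvrmdash")),
      config_fingerprints = list(
        models = config_fingerprint(registry),
        rules = config_fingerprint(rules),
        targets = config_fingerprint(targets)
      )
    ),
    class = "dashboard_payload"
  )
}

#' Serialize a payload to JSON
#'
#' @param payload A `dashboard_payload`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string (invisibly when written to file).
#' @export
payload_json <- function(payload, path = NULL) {
  # serialize via a parse cycle so the representation is canonical:
  # payload -> JSON -> payload -> JSON is bytewise stable
  raw <- jsonlite::toJSON(unclass(payload), auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE)
  json <- jsonlite::toJSON(jsonlite::fromJSON(raw, simplifyVector = FALSE),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Parse a payload back from JSON
#'
#' @param json JSON string or file path.
#' @return A `dashboard_payload`. Round-trips losslessly through
#'   [payload_json()].
#' @export
payload_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(x, class = "dashboard_payload")
}

#' Structurally validate a dashboard payload
#'
#' Checks the payload contract: required top-level sections present and
#' typed, risk in \[0, 1\] when computed, statuses limited to
#' red/green/unknown, every red factor carries a suggestion (or an
#' explicit exemption), imputed fields flagged in the risk estimate, and
#' a failure section present whenever the risk is absent.
#'
#' @param payload A `dashboard_payload` (or one parsed from JSON).
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_payload <- function(payload) {
  v <- character()
  need <- c("patient_id", "index_date", "profile", "selected_model_id",
            "risk", "suggestions", "counterfactuals", "quality",
            "failures", "engine_version", "config_fingerprints")
  miss <- setdiff(need, names(payload))
  if (length(miss)) {
    v <- c(v, sprintf("missing section(s): %s", paste(miss, collapse = ", ")))
  }
  if (!is.character(payload$patient_id) || !nzchar(payload$patient_id)) {
    v <- c(v, "patient_id must be a non-empty string")
  }
  prov <- unlist(payload$profile$provenance)
  if (!all(prov %in% c("observed", "imputed", "missing"))) {
    v <- c(v, "provenance values must be observed/imputed/missing")
  }
  if (!setequal(names(prov), risk_factor_fields())) {
    v <- c(v, "provenance must cover exactly the risk-factor fields")
  }
  statuses <- unlist(payload$statuses)
  if (length(statuses) &&
      !all(statuses %in% c("red", "green", "unknown"))) {
    v <- c(v, "statuses must be red/green/unknown")
  }
  if (!is.null(payload$risk)) {
    r <- payload$risk$risk
    if (!is.numeric(r) || r < 0 || r > 1) {
      v <- c(v, "risk must lie in [0, 1]")
    }
    imputed <- unlist(payload$risk$fields_imputed)
    flagged <- names(prov)[prov == "imputed"]
    if (!all(imputed %in% flagged)) {
      v <- c(v, "fields_imputed must be flagged imputed in provenance")
    }
  } else if (!length(payload$failures)) {
    v <- c(v, "payload without risk must carry a failure section")
  }
  red <- names(statuses)[statuses == "red"]
  suggested <- vapply(payload$suggestions, `[[`, "", "factor")
  unaddressed <- setdiff(red, suggested)
  if (length(unaddressed)) {
    v <- c(v, sprintf("red factor(s) without suggestion: %s",
                      paste(unaddressed, collapse = ", ")))
  }
  comp <- payload$quality$completeness
  if (!is.numeric(comp) || comp < 0 || comp > 1) {
    v <- c(v, "quality completeness must lie in [0, 1]")
  }
  v
}

#' @export
print.dashboard_payload <- function(x, ...) {
  cat(render_consult_note(x), sep = "\n")
  invisible(x)
}
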