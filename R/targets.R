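# Guideline treatment targets and red/green flagging. Targets are data
# (YAML/JSON config), never hard-coded; the shipped file carries clearly
# labelled illustrative defaults with citation links.

DIRECTIONS <- c("below", "above", "equals")

#' Define a treatment target
#'
#' @param factor Profile field the target constrains.
#' @param threshold Target value in the field's canonical units.
#' @param direction `"below"` (green iff value < threshold), `"above"`
#'   (green iff value > threshold) or `"equals"` (green iff value equals
#'   threshold). The boundary itself is red for `below`/`above`.
#' @param applicable_model_ids Model ids the target applies to.
#' @param intervention_id Identifier of the intervention that addresses a
#'   violation (used by scenarios).
#' @param kind `"pharmacological"` or `"lifestyle"`.
#' @param drug_class Therapeutic medication class governing the factor
#'   (used to mark suggestions as intensification vs initiation); may be
#'   `NULL` for lifestyle targets.
#' @param evidence_link URL of the guideline/manuscript backing the
#'   target; required for pharmacological targets.
#' @return A `treatment_target`.
#' @export
treatment_target <- function(factor, threshold, direction,
                             applicable_model_ids, intervention_id,
                             kind = c("pharmacological", "lifestyle"),
                             drug_class = NULL, evidence_link = "") {
  kind <- match.arg(kind)
  if (!factor %in% RISK_FACTOR_FIELDS) {
    schema_error(sprintf("target factor '%s' is not a profile field", factor))
  }
  if (!direction %in% DIRECTIONS) {
    schema_error(sprintf("direction must be one of: %s",
                         paste(DIRECTIONS, collapse = ", ")))
  }
  if (direction != "equals" &&
      (!is.numeric(threshold) || !is.finite(threshold))) {
    schema_error(sprintf("target threshold for '%s' must be finite", factor))
  }
  if (kind == "pharmacological" && !nzchar(evidence_link)) {
    schema_error(sprintf(
      "pharmacological target '%s' needs a non-empty evidence_link",
      intervention_id))
  }
  structure(
    list(factor = factor, threshold = threshold, direction = direction,
         applicable_model_ids = applicable_model_ids,
         intervention_id = intervention_id, kind = kind,
         drug_class = drug_class, evidence_link = evidence_link),
    class = "treatment_target"
  )
}

#' Load treatment targets from YAML/JSON
#' @param path Config file path.
#' @return List of `treatment_target`s (class `treatment_targets`).
#' @export
load_targets <- function(path) {
  raw <- read_config_file(path)
  structure(lapply(raw, function(t) {
    treatment_target(
      factor = t$factor, threshold = t$threshold, direction = t$direction,
      applicable_model_ids = unlist(t$applicable_model_ids),
      intervention_id = t$intervention_id, kind = t$kind,
      drug_class = t$drug_class, evidence_link = t$evidence_link %||% ""
    )
  }), class = "treatment_targets")
}

#' Write treatment targets to YAML/JSON
#' @param targets A `treatment_targets` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  write_config_file(lapply(unclass(targets), unclass), path)
}

#' The shipped treatment-target set
#'
#' Illustrative guideline-style defaults (see `extdata/targets.yaml`):
#' SBP below 140 mmHg for every model; LDL below 2.6 mmol/L for primary
#' prevention (heart_score, advance, elderly) and below 1.8 mmol/L for
#' established CVD (smart); HbA1c below 53 mmol/mol for the diabetes
#' model; smoking target `never`-or-`former` expressed as
#' `equals "non-smoker"` via the lifestyle cessation target. Deployers
#' substitute guideline-authoritative values in config.
#'
#' @return A `treatment_targets` list.
#' @export
default_targets <- function() {
  load_targets(system.file("extdata", "targets.yaml", package = "cvrmdash"))
}

targets_for_model <- function(targets, model_id) {
  Filter(function(t) model_id %in% t$applicable_model_ids, targets)
}

target_status <- function(target, value) {
  if (is.null(value)) return("unknown")
  ok <- switch(target$direction,
    below = value < target$threshold,
    above = value > target$threshold,
    equals = identical(as.character(value), as.character(target$threshold))
  )
  if (ok) "green" else "red"
}

#' Red/green status of each targeted risk factor
#'
#' Each factor that has a target applicable to the selected model gets
#' status `green` (meets the target), `red` (violates it) or `unknown`
#' (no value in the profile). The boundary convention for `below` is:
#' value < threshold is green, value >= threshold is red.
#'
#' @param profile A `risk_profile`.
#' @param model_id The selected model id.
#' @param targets A `treatment_targets` list.
#' @return Named character vector factor -> status.
#' @export
evaluate_targets <- function(profile, model_id,
                             targets = default_targets()) {
  applicable <- targets_for_model(targets, model_id)
  status <- character()
  for (t in applicable) {
    value <- if (profile_has(profile, t$factor)) {
      profile$fields[[t$factor]]
    } else NULL
    status[[t$factor]] <- target_status(t, value)
  }
  status
}

#' Generate treatment suggestions for red risk factors
#'
#' One suggestion per red factor: pharmacological suggestions are marked
#' `already_treated = TRUE` when an active drug of the governing
#' therapeutic class exists (intensify rather than initiate). A current
#' smoker additionally always receives a lifestyle smoking-cessation
#' suggestion. Green and unknown factors yield no suggestion.
#'
#' @param profile A `risk_profile` with medications attached.
#' @param status Status map from [evaluate_targets()].
#' @param targets A `treatment_targets` list.
#' @param model_id The selected model id.
#' @return List of `treatment_suggestion`s: `intervention_id`, `kind`,
#'   `factor`, `current_value`, `target_value`, `already_treated`,
#'   `evidence_link`.
#' @export
suggest_treatments <- function(profile, status, targets = default_targets(),
                               model_id) {
  applicable <- targets_for_model(targets, model_id)
  suggestions <- list()
  for (t in applicable) {
    if (!identical(status[[t$factor]], "red")) next
    treated <- !is.null(t$drug_class) &&
      has_medication_class(profile, t$drug_class)
    suggestions[[length(suggestions) + 1L]] <- structure(
      list(intervention_id = t$intervention_id,
           kind = t$kind,
           factor = t$factor,
           current_value = profile$fields[[t$factor]],
           target_value = t$threshold,
           already_treated = treated,
           evidence_link = t$evidence_link),
      class = "treatment_suggestion")
  }
  if (isTRUE(is_current_smoker(profile)) &&
      !"smoking_cessation" %in%
        vapply(suggestions, `[[`, "", "intervention_id")) {
    suggestions[[length(suggestions) + 1L]] <- structure(
      list(intervention_id = "smoking_cessation",
           kind = "lifestyle",
           factor = "smoking",
           current_value = "current",
           target_value = "former",
           already_treated = FALSE,
           evidence_link = "https://example.org/cvrm-guideline#smoking"),
      class = "treatment_suggestion")
  }
  suggestions
}
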