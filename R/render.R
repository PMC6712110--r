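# Plain-text renderings: the print page and the copy-to-consult block.
# Both are deterministic functions of the payload.

fmt_value <- function(field, value) {
  if (is.null(value)) return("-")
  if (is.logical(value)) return(if (value) "yes" else "no")
  if (is.numeric(value)) {
    u <- tryCatch(canonical_unit(field), error = function(e) "")
    return(trimws(paste(format(value, trim = TRUE), u)))
  }
  as.character(value)
}

status_marker <- function(status) {
  switch(status, red = " [HIGH]", green = " [ok]", unknown = " [?]", "")
}

fmt_risk_pct <- function(risk) sprintf("%.1f%%", 100 * risk)

#' Render the printable dashboard page
#'
#' A deterministic plain-text page: risk factors with red/green markers
#' and provenance notes, active medications indented beneath their
#' governing risk factor, the 10-year risk percentage, treatment
#' suggestions and counterfactual scenarios.
#'
#' @param payload A `dashboard_payload`.
#' @return Character vector of lines.
#' @export
render_print <- function(payload) {
  prov <- unlist(payload$profile$provenance)
  statuses <- unlist(payload$statuses)
  meds <- payload$profile$medications_by_class
  class_of <- medication_class_factors()

  lines <- c(
    sprintf("CVRM dashboard — patient %s — index date %s",
            payload$patient_id, payload$index_date),
    strrep("-", 60),
    "RISK FACTORS")
  for (f in risk_factor_fields()) {
    value <- payload$profile$fields[[f]]
    note <- switch(prov[[f]], imputed = " (imputed)",
                   missing = " (missing)", "")
    marker <- if (f %in% names(statuses)) status_marker(statuses[[f]]) else ""
    lines <- c(lines, sprintf("  %-28s %s%s%s", f, fmt_value(f, value),
                              marker, note))
    governed <- names(class_of)[!is.na(class_of) & class_of == f]
    for (cls in governed) {
      for (drug in meds[[cls]]) {
        lines <- c(lines, sprintf("      %s (%s)", drug,
                                  gsub("_", "-", cls)))
      }
    }
  }
  for (drug in meds[["other"]]) {
    lines <- c(lines, sprintf("  other medication: %s", drug))
  }

  lines <- c(lines, "", "RISK SCORE")
  if (!is.null(payload$risk)) {
    lines <- c(lines, sprintf("  %s: %s 10-year cardiovascular risk",
                              payload$selected_model_id,
                              fmt_risk_pct(payload$risk$risk)))
    imput <- unlist(payload$risk$fields_imputed)
    if (length(imput)) {
      lines <- c(lines, sprintf("  note: estimated using imputed %s",
                                paste(imput, collapse = ", ")))
    }
  } else {
    lines <- c(lines, "  not computable:")
    for (fl in payload$failures) {
      lines <- c(lines, paste0("    ", fl$message))
    }
  }

  lines <- c(lines, "", "TREATMENT SUGGESTIONS")
  if (length(payload$suggestions)) {
    for (s in payload$suggestions) {
      action <- if (isTRUE(s$already_treated)) "intensify" else "initiate"
      lines <- c(lines, sprintf(
        "  %s %s [%s]: %s %s -> target %s",
        action, s$intervention_id, s$kind, s$factor,
        fmt_value(s$factor, s$current_value),
        fmt_value(s$factor, s$target_value)))
    }
  } else {
    lines <- c(lines, "  none — all targeted risk factors on target")
  }

  if (length(payload$counterfactuals)) {
    lines <- c(lines, "", "TREATMENT PROSPECTS (on/off)")
    for (cf in payload$counterfactuals) {
      toggles <- unlist(cf$scenario$toggles)
      lines <- c(lines, sprintf(
        "  [%s] risk %s -> %s (ARR %.1f pp)",
        if (length(toggles)) paste(toggles, collapse = "+") else "none on",
        fmt_risk_pct(cf$baseline_risk), fmt_risk_pct(cf$scenario_risk),
        100 * cf$absolute_risk_reduction))
    }
  }
  lines
}

#' Render the copy-to-consult block
#'
#' A compact block (at most 20 lines) for pasting into a consultation
#' note: selected model, risk, imputed-field caveat and suggestions. For a
#' degraded payload it states that the risk is not computable and names
#' the missing fields.
#'
#' @param payload A `dashboard_payload`.
#' @return Character vector of lines (length <= 20).
#' @export
render_consult_note <- function(payload) {
  lines <- sprintf("CVRM %s:", payload$patient_id)
  if (!is.null(payload$risk)) {
    lines <- c(lines, sprintf("10-y CVD risk %s (%s).",
                              fmt_risk_pct(payload$risk$risk),
                              payload$selected_model_id))
    imput <- unlist(payload$risk$fields_imputed)
    if (length(imput)) {
      lines <- c(lines, sprintf("Caveat: %s imputed (population mean).",
                                paste(imput, collapse = ", ")))
    }
  } else {
    missing <- unique(unlist(lapply(payload$failures, `[[`,
                                    "missing_fields")))
    lines <- c(lines, paste0(
      "Risk not computable; missing: ",
      if (length(missing)) paste(missing, collapse = ", ") else "(see failures)",
      "."))
  }
  if (length(payload$suggestions)) {
    lines <- c(lines, "Advice:")
    for (s in head(payload$suggestions, 10L)) {
      action <- if (isTRUE(s$already_treated)) "intensify" else "initiate"
      lines <- c(lines, sprintf("- %s %s (%s %s, target %s)",
                                action, s$intervention_id, s$factor,
                                fmt_value(s$factor, s$current_value),
                                fmt_value(s$factor, s$target_value)))
    }
  }
  if (length(payload$counterfactuals)) {
    cf <- payload$counterfactuals[[1]]
    lines <- c(lines, sprintf("If adherent: risk %s (ARR %.1f pp).",
                              fmt_risk_pct(cf$scenario_risk),
                              100 * cf$absolute_risk_reduction))
  }
  head(lines, 20L)
}
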