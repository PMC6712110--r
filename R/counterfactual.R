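# Counterfactual risk under on/off intervention toggles: the "risk with or
# without the proposed treatment" view. Two benefit modes:
#   substitute_target — recompute risk with each toggled factor set to its
#     target value ("if treatment goals are adhered to"); the default.
#   hazard_ratio — scale the hazard by the product of per-intervention HRs:
#     S_scenario = S0 ^ (exp(LP - LPbar) * prod(HR)), the standard
#     proportional-hazards composition (independent interventions assumed).

#' Define an intervention scenario
#'
#' @param toggles Character vector of intervention ids switched on; each
#'   must exist in the suggestion list the scenario is applied against.
#' @param mode `"substitute_target"` (default) or `"hazard_ratio"`.
#' @param hazard_ratios Named numeric vector intervention_id -> HR (> 0);
#'   required for every toggled intervention in `hazard_ratio` mode.
#' @return A `scenario` object.
#' @export
scenario <- function(toggles = character(),
                     mode = c("substitute_target", "hazard_ratio"),
                     hazard_ratios = NULL) {
  mode <- match.arg(mode)
  toggles <- as.character(toggles)
  if (mode == "hazard_ratio") {
    missing_hr <- setdiff(toggles, names(hazard_ratios))
    if (length(missing_hr)) {
      scenario_error(sprintf("hazard_ratio mode lacks HR for: %s",
                             paste(missing_hr, collapse = ", ")))
    }
    if (any(!is.finite(hazard_ratios) | hazard_ratios <= 0)) {
      scenario_error("hazard ratios must be finite and > 0")
    }
  }
  structure(list(toggles = toggles, mode = mode,
                 hazard_ratios = hazard_ratios),
            class = "scenario")
}

match_toggles <- function(scen, suggestions) {
  ids <- vapply(suggestions, `[[`, "", "intervention_id")
  unknown <- setdiff(scen$toggles, ids)
  if (length(unknown)) {
    scenario_error(sprintf("toggle references unknown intervention(s): %s",
                           paste(unknown, collapse = ", ")),
                   interventions = unknown)
  }
  suggestions[match(scen$toggles, ids)]
}

#' Apply a scenario to a profile
#'
#' In `substitute_target` mode each toggled-on intervention sets its
#' factor to the suggestion's target value (smoking cessation sets the
#' smoking status to `former`, clearing the current-smoker indicator);
#' untouched fields are unchanged and the input profile is never mutated.
#' In `hazard_ratio` mode the profile is returned unchanged — the effect
#' is applied on the hazard scale by [counterfactual_risk()].
#'
#' @param profile A `risk_profile`.
#' @param scen A [scenario()].
#' @param suggestions Suggestion list from [suggest_treatments()].
#' @return The modified `risk_profile` (a copy).
#' @export
apply_scenario <- function(profile, scen, suggestions) {
  stopifnot(inherits(profile, "risk_profile"), inherits(scen, "scenario"))
  toggled <- match_toggles(scen, suggestions)
  if (scen$mode == "hazard_ratio") return(profile)
  out <- profile
  for (s in toggled) {
    if (s$factor == "smoking") {
      out$fields$smoking <- "former"
    } else {
      out$fields[[s$factor]] <- as.numeric(s$target_value)
    }
  }
  out
}

#' Counterfactual risk under a scenario
#'
#' Computes the baseline 10-year risk, the risk under the scenario, the
#' absolute risk reduction (ARR = baseline - scenario) and the relative
#' reduction (ARR / baseline; reported as `NA` — undefined, not 0 — when
#' the baseline risk is 0).
#'
#' @param profile A `risk_profile` (all required model fields present or
#'   imputed).
#' @param scen A [scenario()].
#' @param definition The selected [risk_model()].
#' @param suggestions Suggestion list from [suggest_treatments()].
#' @return A `counterfactual_result`: `baseline_risk`, `scenario_risk`,
#'   `absolute_risk_reduction`, `relative_reduction`, `scenario`.
#' @export
counterfactual_risk <- function(profile, scen, definition, suggestions) {
  baseline <- ten_year_risk(profile, definition)
  if (scen$mode == "substitute_target") {
    modified <- apply_scenario(profile, scen, suggestions)
    scen_risk <- ten_year_risk(modified, definition)$risk
  } else {
    toggled <- match_toggles(scen, suggestions)
    hr_prod <- prod(scen$hazard_ratios[
      vapply(toggled, `[[`, "", "intervention_id")])
    lp <- baseline$linear_predictor
    s_scen <- definition$baseline_survival ^
      (exp(lp - definition$mean_linear_predictor) * hr_prod)
    scen_risk <- 1 - s_scen
  }
  arr <- baseline$risk - scen_risk
  structure(
    list(baseline_risk = baseline$risk,
         scenario_risk = scen_risk,
         absolute_risk_reduction = arr,
         relative_reduction = if (baseline$risk == 0) NA_real_
                              else arr / baseline$risk,
         scenario = scen),
    class = "counterfactual_result"
  )
}

#' @export
print.counterfactual_result <- function(x, ...) {
  cat(sprintf(
    "<counterfactual_result> baseline %.1f%% -> scenario %.1f%% (ARR %.1f pp)\n",
    100 * x$baseline_risk, 100 * x$scenario_risk,
    100 * x$absolute_risk_reduction))
  cat("  toggles:", if (length(x$scenario$toggles))
    paste(x$scenario$toggles, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
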