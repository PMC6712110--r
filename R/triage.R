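# Business-rule decision tree: assign each profile to exactly one risk
# model. Rules are declarative config (priority, predicate, model_id);
# the first matching rule by priority wins. Triage fields (age, prior_cvd,
# diabetes) are never imputed.

PREDICATE_KEYS <- c("min_age", "max_age", "prior_cvd", "diabetes")

#' Define one triage rule
#'
#' @param priority Integer rank; lower numbers are tried first and must be
#'   unique within a rule set.
#' @param predicate Named list of conditions over triage fields: `min_age`
#'   (inclusive), `max_age` (exclusive), `prior_cvd` (logical), `diabetes`
#'   (logical). An empty predicate matches every profile (catch-all).
#' @param model_id Target model id.
#' @return A `triage_rule`.
#' @export
triage_rule <- function(priority, predicate = list(), model_id) {
  bad <- setdiff(names(predicate), PREDICATE_KEYS)
  if (length(bad)) {
    schema_error(sprintf("predicate references unknown key(s): %s",
                         paste(bad, collapse = ", ")))
  }
  structure(list(priority = as.integer(priority), predicate = predicate,
                 model_id = model_id),
            class = "triage_rule")
}

#' Build an ordered triage rule set
#'
#' @param rules List of [triage_rule()]s; priorities must be unique.
#' @return A `triage_rules` object ordered by priority.
#' @export
triage_rules <- function(rules) {
  prios <- vapply(rules, `[[`, integer(1), "priority")
  if (anyDuplicated(prios)) {
    schema_error("triage rule priorities must be unique")
  }
  structure(rules[order(prios)], class = "triage_rules")
}

predicate_fields <- function(predicate) {
  out <- character()
  if (!is.null(predicate$min_age) || !is.null(predicate$max_age)) {
    out <- c(out, "age")
  }
  if (!is.null(predicate$prior_cvd)) out <- c(out, "prior_cvd")
  if (!is.null(predicate$diabetes)) out <- c(out, "diabetes")
  out
}

rule_matches <- function(rule, age, prior_cvd, diabetes) {
  p <- rule$predicate
  if (!is.null(p$min_age) && age < p$min_age) return(FALSE)
  if (!is.null(p$max_age) && age >= p$max_age) return(FALSE)
  if (!is.null(p$prior_cvd) && !identical(prior_cvd, p$prior_cvd)) return(FALSE)
  if (!is.null(p$diabetes) && !identical(diabetes, p$diabetes)) return(FALSE)
  TRUE
}

#' Select the risk model for a profile
#'
#' Applies the rules in priority order; the first match wins. The default
#' rule set assigns: age >= 70 to `elderly`; prior cardiovascular events to
#' `smart`; diabetes without prior CVD to `advance`; everyone else to
#' `heart_score`. Missing triage fields are an error — model choice must
#' rest on observed data, so triage fields are never imputed.
#'
#' @param profile A `risk_profile`.
#' @param rules A [triage_rules()] set (default: shipped rules).
#' @return The selected model id (length-1 character).
#' @export
select_model <- function(profile, rules = default_triage_rules()) {
  stopifnot(inherits(profile, "risk_profile"), inherits(rules, "triage_rules"))
  if (!length(rules)) triage_error("triage rule set is empty")
  needed <- unique(unlist(lapply(rules, function(r) {
    predicate_fields(r$predicate)
  })))
  absent <- needed[!vapply(needed, profile_has, TRUE, profile = profile)]
  if (length(absent)) missing_triage_field_error(absent)
  age <- profile$fields$age
  prior_cvd <- profile$fields$prior_cvd
  diabetes <- profile$fields$diabetes
  for (rule in rules) {
    if (rule_matches(rule, age, prior_cvd, diabetes)) return(rule$model_id)
  }
  triage_error("no triage rule matches the profile")
}

#' Exhaustively validate a triage rule set
#'
#' Enumerates every combination of the triage-field domains (age bucketed
#' at the rule thresholds, prior CVD yes/no, diabetes yes/no), records the
#' winning rule for each, and flags uncovered combinations and unreachable
#' rules. Report-only: no errors are raised.
#'
#' @param rules A [triage_rules()] set.
#' @param age_points Representative ages, one per age bucket. By default
#'   derived from the age thresholds appearing in the rules (a point below
#'   and at/above each threshold).
#' @return A `triage_partition_report`: `combinations` (data frame with
#'   age, prior_cvd, diabetes, model_id, rule_priority), `uncovered`
#'   (data frame of unmatched combinations), `unreachable` (priorities of
#'   rules that never win), `total`, `covered`.
#' @export
validate_rule_set <- function(rules, age_points = NULL) {
  stopifnot(inherits(rules, "triage_rules"))
  if (is.null(age_points)) {
    thresholds <- sort(unique(unlist(lapply(rules, function(r) {
      c(r$predicate$min_age, r$predicate$max_age)
    }))))
    if (!length(thresholds)) thresholds <- 70
    age_points <- sort(unique(c(thresholds[1] - 10, thresholds)))
  }
  grid <- expand.grid(age = age_points, prior_cvd = c(FALSE, TRUE),
                      diabetes = c(FALSE, TRUE),
                      KEEP.OUT.ATTRS = FALSE)
  grid$model_id <- NA_character_
  grid$rule_priority <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    for (rule in rules) {
      if (rule_matches(rule, grid$age[i], grid$prior_cvd[i],
                       grid$diabetes[i])) {
        grid$model_id[i] <- rule$model_id
        grid$rule_priority[i] <- rule$priority
        break
      }
    }
  }
  winners <- unique(grid$rule_priority[!is.na(grid$rule_priority)])
  unreachable <- setdiff(vapply(rules, `[[`, integer(1), "priority"), winners)
  structure(
    list(combinations = grid,
         uncovered = grid[is.na(grid$model_id),
                          c("age", "prior_cvd", "diabetes"), drop = FALSE],
         unreachable = unreachable,
         total = nrow(grid),
         covered = sum(!is.na(grid$model_id))),
    class = "triage_partition_report"
  )
}

#' @export
print.triage_partition_report <- function(x, ...) {
  cat(sprintf("<triage_partition_report> %d/%d combinations covered\n",
              x$covered, x$total))
  print(x$combinations)
  if (nrow(x$uncovered)) {
    cat("uncovered combinations:\n"); print(x$uncovered)
  }
  if (length(x$unreachable)) {
    cat("unreachable rule priorities:",
        paste(x$unreachable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a triage rule set from YAML/JSON
#' @param path Config file path.
#' @return A `triage_rules` object.
#' @export
load_triage_rules <- function(path) {
  raw <- read_config_file(path)
  triage_rules(lapply(raw, function(r) {
    triage_rule(priority = r$priority, predicate = r$predicate %||% list(),
                model_id = r$model_id)
  }))
}

#' Write a triage rule set to YAML/JSON
#' @param rules A `triage_rules` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triage_rules <- function(rules, path) {
  write_config_file(lapply(unclass(rules), unclass), path)
}

#' The shipped triage rule set
#'
#' Priority order: Elderly (age >= 70, inclusive) over SMART (prior CVD)
#' over ADVANCE (diabetes, no prior CVD) over the primary-prevention
#' heart_score catch-all. Precedence between overlapping categories (an
#' elderly patient with prior CVD, an elderly diabetic) is a documented
#' configuration default, editable in `extdata/rules.yaml`.
#'
#' @return A `triage_rules` object.
#' @export
default_triage_rules <- function() {
  load_triage_rules(system.file("extdata", "rules.yaml",
                                package = "cvrmdash"))
}
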