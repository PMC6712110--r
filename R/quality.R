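# Data-quality metrics (completeness, accuracy) and mean imputation with
# provenance tracking.

#' Completeness of a risk profile
#'
#' Proportion of information provided versus information needed: the count
#' of required fields with provenance `observed` divided by the count of
#' required fields. Imputed fields do not count as provided — the metric
#' deliberately predates imputation; report post-imputation availability
#' separately if needed (see [build_dashboard()]'s quality section).
#'
#' @param profile A `risk_profile`.
#' @param required_fields Non-empty character vector of field names.
#' @return Proportion in \[0, 1\].
#' @export
completeness <- function(profile, required_fields) {
  if (!length(required_fields)) config_error("required_fields is empty")
  mean(profile$provenance[required_fields] == "observed")
}

values_agree <- function(a, b, tol) {
  if (is.numeric(a) && is.numeric(b)) {
    if (!is.null(tol)) return(abs(a - b) <= tol)
    # default: exact for integers, 1e-9 relative for reals
    if (a == round(a) && b == round(b)) return(a == b)
    denom <- max(abs(a), abs(b))
    if (denom == 0) return(TRUE)
    abs(a - b) / denom <= 1e-9
  } else {
    identical(as.character(a), as.character(b))
  }
}

#' Accuracy: agreement between dashboard values and raw source values
#'
#' Per shared key, a numeric pair agrees within tolerance (default: exact
#' for integer-valued pairs, 1e-9 relative otherwise); categorical values
#' agree by equality. Accuracy = agreeing / compared.
#'
#' @param dashboard_values Named list/vector of values as presented.
#' @param raw_values Named list/vector of the raw source values.
#' @param tolerance Optional named numeric vector of per-field absolute
#'   tolerances.
#' @return List: `accuracy` (NA when nothing compared), `n_compared`,
#'   `n_agree`, `disagreeing` (keys), `undefined` (TRUE when
#'   `n_compared == 0`).
#' @export
accuracy <- function(dashboard_values, raw_values, tolerance = NULL) {
  keys <- intersect(names(dashboard_values), names(raw_values))
  agree <- vapply(keys, function(k) {
    values_agree(dashboard_values[[k]], raw_values[[k]],
                 if (k %in% names(tolerance)) tolerance[[k]] else NULL)
  }, TRUE)
  n <- length(keys)
  list(
    accuracy = if (n == 0) NA_real_ else sum(agree) / n,
    n_compared = n,
    n_agree = sum(agree),
    disagreeing = keys[!agree],
    undefined = n == 0
  )
}

#' Fit a mean-imputation model on a cohort
#'
#' Per-field arithmetic mean over the profiles where the field is observed
#' (imputed values in the training profiles are ignored). Fields observed
#' nowhere get no mean and remain unfillable.
#'
#' @param cohort Non-empty list of `risk_profile`s.
#' @param fields Fields to train means for (default: all numeric risk
#'   factors).
#' @return An `imputation_model`: `training_means`, `training_n`,
#'   `provenance_note`.
#' @export
fit_imputation_model <- function(cohort, fields = NUMERIC_FIELDS) {
  if (!length(cohort)) config_error("cohort is empty")
  means <- list()
  n <- list()
  for (f in fields) {
    vals <- unlist(lapply(cohort, function(p) {
      if (identical(p$provenance[[f]], "observed")) p$fields[[f]] else NULL
    }))
    if (length(vals)) {
      means[[f]] <- mean(vals)
      n[[f]] <- length(vals)
    }
  }
  structure(
    list(training_means = means, training_n = n,
         provenance_note = sprintf(
           "per-field means over %d training profiles", length(cohort))),
    class = "imputation_model"
  )
}

#' Impute missing needed fields with training means
#'
#' Missing fields among `fields_needed` are filled with the model's
#' training mean and their provenance set to `imputed`; observed values
#' are never overwritten. Needed fields without a trained mean remain
#' missing and are reported in the `"unfilled"` attribute of the result
#' (they surface downstream as missing-data errors).
#'
#' @param profile A `risk_profile`.
#' @param model An [fit_imputation_model()] result.
#' @param fields_needed Fields the downstream risk model requires.
#' @return The profile with fills applied; `attr(, "unfilled")` lists
#'   needed fields that could not be filled.
#' @export
impute <- function(profile, model, fields_needed) {
  stopifnot(inherits(profile, "risk_profile"),
            inherits(model, "imputation_model"))
  unfilled <- character()
  for (f in fields_needed) {
    if (profile_has(profile, f)) next
    m <- model$training_means[[f]]
    if (is.null(m)) {
      unfilled <- c(unfilled, f)
    } else {
      profile <- set_field(profile, f, m, "imputed")
    }
  }
  attr(profile, "unfilled") <- unfilled
  profile
}

#' Load an imputation model from YAML/JSON
#' @param path Config file path.
#' @return An `imputation_model`.
#' @export
load_imputation_model <- function(path) {
  raw <- read_config_file(path)
  structure(list(training_means = lapply(raw$training_means, as.numeric),
                 training_n = lapply(raw$training_n, as.integer),
                 provenance_note = raw$provenance_note %||% ""),
            class = "imputation_model")
}

#' Write an imputation model to YAML/JSON
#' @param model An `imputation_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imputation_model <- function(model, path) {
  write_config_file(unclass(model), path)
}
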