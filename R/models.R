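# Declarative Cox-form 10-year risk models. A definition is data, not
# code: risk = 1 - S0(10) ^ exp(LP - LPbar), with
# LP = sum over predictors of coefficient * transform(field value).
# Transform vocabulary: identity, log, centered, indicator.

TRANSFORMS <- c("identity", "log", "centered", "indicator")

#' Define a Cox-form risk model
#'
#' @param model_id Unique identifier (the four shipped slots are
#'   `heart_score`, `smart`, `advance`, `elderly`; any other id may be
#'   registered).
#' @param predictors List of predictor specs, each a list with `field`
#'   (a [risk_factor_fields()] name), `transform` (one of `identity`,
#'   `log`, `centered`, `indicator`), `coefficient`, and optionally
#'   `reference` (centering value, required for `centered`) or `level`
#'   (the value the `indicator` matches; defaults to TRUE for logical
#'   fields).
#' @param baseline_survival Event-free probability S0 at the horizon for
#'   the reference covariate profile; strictly in (0, 1).
#' @param mean_linear_predictor Population mean of the linear predictor
#'   (LP is centered on it before exponentiation).
#' @param horizon Risk horizon in years (default 10).
#' @param required_fields Profile fields that must be present (observed or
#'   imputed) before evaluation; defaults to the predictor fields and must
#'   be a superset of them.
#' @param citation Free-text/URL pointer to the published source of the
#'   coefficients.
#' @return A `risk_model` object.
#' @export
risk_model <- function(model_id, predictors, baseline_survival,
                       mean_linear_predictor = 0, horizon = 10,
                       required_fields = NULL, citation = "") {
  if (!is.character(model_id) || length(model_id) != 1L || !nzchar(model_id)) {
    schema_error("model_id must be a non-empty string")
  }
  if (!is.numeric(baseline_survival) || length(baseline_survival) != 1L ||
      !is.finite(baseline_survival) ||
      baseline_survival <= 0 || baseline_survival >= 1) {
    schema_error(sprintf("baseline_survival must be strictly in (0,1), got %s",
                         format(baseline_survival)))
  }
  if (!is.numeric(mean_linear_predictor) || !is.finite(mean_linear_predictor)) {
    schema_error("mean_linear_predictor must be a finite number")
  }
  predictors <- lapply(predictors, validate_predictor)
  pred_fields <- vapply(predictors, `[[`, "", "field")
  if (anyDuplicated(pred_fields)) {
    schema_error("duplicate predictor fields in model definition")
  }
  if (is.null(required_fields)) {
    required_fields <- pred_fields
  } else if (!all(pred_fields %in% required_fields)) {
    schema_error("required_fields must contain every predictor field")
  }
  if (!all(required_fields %in% RISK_FACTOR_FIELDS)) {
    schema_error(sprintf("unknown profile field(s): %s",
                         paste(setdiff(required_fields, RISK_FACTOR_FIELDS),
                               collapse = ", ")))
  }
  structure(
    list(model_id = model_id, horizon = horizon, predictors = predictors,
         baseline_survival = baseline_survival,
         mean_linear_predictor = mean_linear_predictor,
         required_fields = required_fields, citation = citation),
    class = "risk_model"
  )
}

validate_predictor <- function(p) {
  if (is.null(p$field) || !p$field %in% RISK_FACTOR_FIELDS) {
    schema_error(sprintf("predictor references unknown profile field '%s'",
                         if (is.null(p$field)) "<none>" else p$field))
  }
  if (is.null(p$transform) || !p$transform %in% TRANSFORMS) {
    schema_error(sprintf("unknown transform '%s' (allowed: %s)",
                         if (is.null(p$transform)) "<none>" else p$transform,
                         paste(TRANSFORMS, collapse = ", ")))
  }
  if (is.null(p$coefficient) || !is.finite(as.numeric(p$coefficient))) {
    schema_error(sprintf("predictor '%s' needs a finite coefficient", p$field))
  }
  p$coefficient <- as.numeric(p$coefficient)
  if (p$transform == "centered") {
    if (is.null(p$reference) || !is.finite(as.numeric(p$reference))) {
      schema_error(sprintf("centered predictor '%s' needs a reference value",
                           p$field))
    }
    p$reference <- as.numeric(p$reference)
  }
  if (p$transform == "indicator" && is.null(p$level)) {
    p$level <- TRUE
  }
  p[intersect(c("field", "transform", "coefficient", "reference", "level"),
              names(p))]
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (%d-year horizon)\n", x$model_id, x$horizon))
  cat(sprintf("  S0(%d) = %g, mean LP = %g\n", x$horizon,
              x$baseline_survival, x$mean_linear_predictor))
  for (p in x$predictors) {
    extra <- if (p$transform == "centered") {
      sprintf(" (ref %g)", p$reference)
    } else if (p$transform == "indicator") {
      sprintf(" (level %s)", format(p$level))
    } else ""
    cat(sprintf("  %+.4f * %s[%s]%s\n", p$coefficient, p$field,
                p$transform, extra))
  }
  invisible(x)
}

# ---- registry ---------------------------------------------------------

#' Create an empty model registry
#' @return A `model_registry` (named list of `risk_model`s).
#' @export
model_registry <- function() {
  structure(list(), class = "model_registry")
}

#' Register a model definition
#'
#' @param registry A `model_registry`.
#' @param definition A [risk_model()].
#' @return The registry with the model added.
#' @export
register_model <- function(registry, definition) {
  stopifnot(inherits(registry, "model_registry"),
            inherits(definition, "risk_model"))
  if (definition$model_id %in% names(registry)) {
    registration_error(sprintf("model id '%s' already registered",
                               definition$model_id))
  }
  registry[[definition$model_id]] <- definition
  registry
}

#' Retrieve a model by id
#' @param registry A `model_registry`.
#' @param model_id Model identifier.
#' @return The `risk_model`.
#' @export
get_model <- function(registry, model_id) {
  m <- registry[[model_id]]
  if (is.null(m)) {
    registration_error(sprintf("model id '%s' not in registry", model_id))
  }
  m
}

#' List registered model ids
#' @param registry A `model_registry`.
#' @return Character vector of model ids.
#' @export
list_models <- function(registry) names(registry)

#' Load a model registry from a YAML or JSON file
#'
#' @param path File path; a mapping model_id -> definition, or a list of
#'   definitions each carrying its `model_id`.
#' @return A `model_registry`.
#' @export
load_model_registry <- function(path) {
  raw <- read_config_file(path)
  registry <- model_registry()
  for (i in seq_along(raw)) {
    def <- raw[[i]]
    if (is.null(def$model_id)) def$model_id <- names(raw)[i]
    registry <- register_model(registry, risk_model(
      model_id = def$model_id,
      predictors = def$predictors,
      baseline_survival = def$baseline_survival,
      mean_linear_predictor = def$mean_linear_predictor %||% 0,
      horizon = def$horizon %||% 10,
      required_fields = unlist(def$required_fields) %||% NULL,
      citation = def$citation %||% ""
    ))
  }
  registry
}

#' Write a model registry to a YAML or JSON file
#'
#' The written file round-trips losslessly through
#' [load_model_registry()].
#'
#' @param registry A `model_registry`.
#' @param path Output path; format chosen by extension (.yaml/.yml/.json).
#' @return `path`, invisibly.
#' @export
write_model_registry <- function(registry, path) {
  out <- lapply(unclass(registry), unclass)
  write_config_file(out, path)
}

#' The shipped model registry
#'
#' Four 10-year risk-model slots matching the subpopulations of the
#' business rules: `heart_score` (primary prevention, no prior CVD),
#' `smart` (established cardiovascular disease), `advance` (diabetes, no
#' prior CVD), `elderly` (age 70 or above). The coefficients, centering
#' references and baseline survivals shipped in `extdata/models.yaml` are
#' clearly labelled illustrative values; the `citation` field of each
#' definition points at the published score a deployer should take
#' authoritative coefficients from (they substitute in config, not code).
#'
#' @return A `model_registry` with the four slots.
#' @export
default_model_registry <- function() {
  load_model_registry(system.file("extdata", "models.yaml",
                                  package = "cvrmdash"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_file <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config_file <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# ---- evaluation -------------------------------------------------------

transform_value <- function(p, value) {
  switch(p$transform,
    identity = as.numeric(value),
    log = {
      v <- as.numeric(value)
      if (v <= 0) {
        integrity_error(sprintf("log transform needs positive '%s', got %g",
                                p$field, v))
      }
      log(v)
    },
    centered = as.numeric(value) - p$reference,
    indicator = as.numeric(indicator_matches(p, value))
  )
}

indicator_matches <- function(p, value) {
  if (is.logical(p$level)) {
    isTRUE(as.logical(value) == p$level)
  } else {
    identical(as.character(value), as.character(p$level))
  }
}

# Field value a model consumes: smoking enters models through the binary
# current-smoker indicator.
model_field_value <- function(profile, field) {
  profile$fields[[field]]
}

#' Linear predictor of a model on a profile
#'
#' LP = sum of coefficient x transform(field value) over the model's
#' predictors. All required fields must be present (observed or imputed);
#' the caller imputes first.
#'
#' @param profile A `risk_profile`.
#' @param definition A [risk_model()].
#' @return The dimensionless linear predictor.
#' @export
linear_predictor <- function(profile, definition) {
  stopifnot(inherits(profile, "risk_profile"),
            inherits(definition, "risk_model"))
  absent <- definition$required_fields[
    !vapply(definition$required_fields, profile_has, TRUE,
            profile = profile)]
  if (length(absent)) missing_data_error(absent)
  contribs <- vapply(definition$predictors, function(p) {
    p$coefficient * transform_value(p, model_field_value(profile, p$field))
  }, numeric(1))
  sum(contribs)
}

#' Ten-year cardiovascular risk of a profile under a model
#'
#' risk = 1 - S0(horizon) ^ exp(LP - mean LP), the standard Cox-equation
#' form of published cardiovascular risk scores.
#'
#' @param profile A `risk_profile`.
#' @param definition A [risk_model()].
#' @return A `risk_estimate`: `model_id`, `risk` in \[0,1\],
#'   `linear_predictor`, `fields_used`, `fields_imputed`.
#' @export
ten_year_risk <- function(profile, definition) {
  lp <- linear_predictor(profile, definition)
  risk <- 1 - definition$baseline_survival ^
    exp(lp - definition$mean_linear_predictor)
  fields_used <- definition$required_fields
  structure(
    list(model_id = definition$model_id,
         risk = risk,
         linear_predictor = lp,
         fields_used = fields_used,
         fields_imputed = fields_used[
           profile$provenance[fields_used] == "imputed"]),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("<risk_estimate> %s: %.1f%% 10-year risk (LP = %.4f)\n",
              x$model_id, 100 * x$risk, x$linear_predictor))
  if (length(x$fields_imputed)) {
    cat("  imputed:", paste(x$fields_imputed, collapse = ", "), "\n")
  }
  invisible(x)
}
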