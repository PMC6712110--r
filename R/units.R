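# Unit normalization. Each numeric field has one canonical unit; accepted
# units convert by an affine map canonical = scale * value + offset.
# The table ships as YAML config; unknown units are an error, never a guess.

#' Load a unit-normalization table
#'
#' The table maps each numeric risk-factor field to its canonical unit and
#' the accepted input units with affine conversion (scale, offset). The
#' default table accepts mg/dL for cholesterol fractions (x 0.02586 to
#' mmol/L), DCCT \% for HbA1c (IFCC conversion to mmol/mol) and mg/dL for
#' urine protein (x 0.01 to g/L).
#'
#' @param path Path to a YAML unit table. Defaults to the table shipped
#'   with the package.
#' @return A named list (class `unit_table`): per field, `canonical` and
#'   `accepted` (unit -> list(scale, offset)).
#' @export
load_unit_table <- function(path = system.file("extdata", "units.yaml",
                                               package = "cvrmdash")) {
  if (!nzchar(path) || !file.exists(path)) {
    config_error("unit table file not found")
  }
  tab <- yaml::read_yaml(path)
  for (field in names(tab)) {
    entry <- tab[[field]]
    if (is.null(entry$canonical) || is.null(entry$accepted)) {
      config_error(sprintf("unit table entry '%s' lacks canonical/accepted",
                           field))
    }
  }
  structure(tab, class = "unit_table")
}

#' Default unit table
#' @return The shipped `unit_table`.
#' @export
default_unit_table <- function() {
  load_unit_table()
}

#' Convert a value to a field's canonical unit
#'
#' @param field Profile field name.
#' @param value Numeric value.
#' @param unit Unit string as found in the source stream. An empty or NA
#'   unit is taken to already be canonical.
#' @param units A `unit_table` (default: shipped table).
#' @return Numeric value in the canonical unit.
#' @export
convert_unit <- function(field, value, unit,
                         units = default_unit_table()) {
  entry <- units[[field]]
  if (is.null(entry)) {
    return(as.numeric(value))  # field has no unit dimension (e.g. age)
  }
  if (is.na(unit) || !nzchar(unit)) {
    return(as.numeric(value))
  }
  conv <- entry$accepted[[unit]]
  if (is.null(conv)) {
    unit_error(field, unit)
  }
  as.numeric(conv$scale) * as.numeric(value) + as.numeric(conv$offset)
}

#' Canonical unit of a field
#'
#' @param field Profile field name.
#' @param units A `unit_table`.
#' @return Unit string, or `""` for dimensionless/unitless fields.
#' @export
canonical_unit <- function(field, units = default_unit_table()) {
  entry <- units[[field]]
  if (is.null(entry)) "" else entry$canonical
}
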