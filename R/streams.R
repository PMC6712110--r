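# Stream ingestion: the four EHR-style extraction streams in two dialects.
# Dialect "a": a directory with questionnaire.csv, measurements.csv,
# labs.csv, medications.csv. Dialect "b": one JSON document (an array of
# per-patient bundles). Both round-trip through the same patient_record.

STREAM_HEADERS <- list(
  questionnaire = c("patient_id", "item_code", "value", "timestamp"),
  measurements  = c("patient_id", "measure_code", "value", "unit", "timestamp"),
  labs          = c("patient_id", "analyte_code", "value", "unit", "timestamp"),
  medications   = c("patient_id", "class_code", "drug_name", "start_date",
                    "active")
)

parse_date_col <- function(x, file, col) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    format_error(sprintf(
      "%s: unparseable date '%s' in column '%s' (line %d)",
      file, x[bad[1]], col, bad[1] + 1L), file = file, line = bad[1] + 1L)
  }
  out
}

parse_num_col <- function(x, file, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    format_error(sprintf(
      "%s: non-numeric value '%s' in column '%s' (line %d)",
      file, x[bad[1]], col, bad[1] + 1L), file = file, line = bad[1] + 1L)
  }
  out
}

parse_logical_value <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  ifelse(lx %in% c("true", "yes", "1", "t"), TRUE,
         ifelse(lx %in% c("false", "no", "0", "f"), FALSE, NA))
}

read_stream_csv <- function(path, stream) {
  wanted <- STREAM_HEADERS[[stream]]
  if (!file.exists(path)) {
    format_error(sprintf("stream file not found: %s", path), file = path)
  }
  df <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) format_error(
      sprintf("%s: cannot parse CSV: %s", path, conditionMessage(e)),
      file = path)
  )
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols)) {
    format_error(sprintf("%s: missing column(s): %s", path,
                         paste(missing_cols, collapse = ", ")),
                 file = path)
  }
  df <- df[, wanted, drop = FALSE]
  if (stream %in% c("measurements", "labs")) {
    df$value <- parse_num_col(df$value, path, "value")
    df$timestamp <- parse_date_col(df$timestamp, path, "timestamp")
  } else if (stream == "questionnaire") {
    df$timestamp <- parse_date_col(df$timestamp, path, "timestamp")
  } else {
    df$start_date <- parse_date_col(df$start_date, path, "start_date")
    act <- parse_logical_value(df$active)
    bad <- which(is.na(act) & nzchar(df$active))
    if (length(bad)) {
      format_error(sprintf(
        "%s: non-boolean value '%s' in column 'active' (line %d)",
        path, df$active[bad[1]], "active", bad[1] + 1L), file = path)
    }
    df$active <- act
  }
  df
}

# Duplicate (patient, code, timestamp) keys are legitimate re-registrations
# when the value agrees; conflicting values are an integrity error.
check_stream_integrity <- function(df, code_col, time_col, stream) {
  if (!nrow(df)) return(invisible(df))
  key <- paste(df$patient_id, df[[code_col]], df[[time_col]], sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    vals <- unique(as.character(df$value[key == k]))
    if (length(vals) > 1L) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      integrity_error(sprintf(
        "conflicting values %s for patient %s, code %s, timestamp %s in %s stream",
        paste(shQuote(vals), collapse = " vs "),
        parts[1], parts[2], parts[3], stream))
    }
  }
  invisible(df)
}

#' Extract patient records from the four raw streams
#'
#' Reads the four EHR-style extraction streams (questionnaire information,
#' measurements, laboratory results, medication register) and returns one
#' [patient_record()] per distinct patient id. Unknown item codes are
#' retained in the record but flagged (`recognized = FALSE`). Duplicate
#' (patient, code, timestamp) entries with conflicting values raise an
#' integrity error.
#'
#' @param source For dialect `"a"`, a directory containing
#'   `questionnaire.csv`, `measurements.csv`, `labs.csv`,
#'   `medications.csv`; for dialect `"b"`, the path of a JSON file holding
#'   an array of per-patient bundles.
#' @param dialect `"a"` (four CSV files) or `"b"` (one JSON document).
#' @return A named list of `patient_record` objects (names are patient ids,
#'   sorted).
#' @export
extract_streams <- function(source, dialect = c("a", "b")) {
  dialect <- match.arg(dialect)
  if (dialect == "a") {
    streams <- lapply(setNames(nm = names(STREAM_HEADERS)), function(s) {
      read_stream_csv(file.path(source, paste0(s, ".csv")), s)
    })
  } else {
    streams <- read_bundle_json(source)
  }
  check_stream_integrity(streams$questionnaire, "item_code", "timestamp",
                         "questionnaire")
  check_stream_integrity(streams$measurements, "measure_code", "timestamp",
                         "measurements")
  check_stream_integrity(streams$labs, "analyte_code", "timestamp", "labs")

  ids <- sort(unique(c(streams$questionnaire$patient_id,
                       streams$measurements$patient_id,
                       streams$labs$patient_id,
                       streams$medications$patient_id)))
  if (any(!nzchar(ids) | is.na(ids))) {
    integrity_error("empty patient_id in input streams")
  }
  records <- lapply(ids, function(id) {
    patient_record(
      patient_id = id,
      questionnaire = drop_id(streams$questionnaire, id),
      measurements = drop_id(streams$measurements, id),
      labs = drop_id(streams$labs, id),
      medications = drop_id(streams$medications, id)
    )
  })
  setNames(records, ids)
}

drop_id <- function(df, id) {
  out <- df[df$patient_id == id, setdiff(names(df), "patient_id"),
            drop = FALSE]
  rownames(out) <- NULL
  out
}

read_bundle_json <- function(path) {
  if (!file.exists(path)) {
    format_error(sprintf("bundle file not found: %s", path), file = path)
  }
  bundles <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) format_error(
      sprintf("%s: cannot parse JSON: %s", path, conditionMessage(e)),
      file = path)
  )
  if (!is.null(bundles$patient_id)) bundles <- list(bundles)
  streams <- lapply(setNames(nm = names(STREAM_HEADERS)), function(s) {
    rows <- lapply(bundles, function(b) {
      entries <- b[[s]]
      if (is.null(entries) || !length(entries)) return(NULL)
      do.call(rbind, lapply(entries, function(e) {
        e <- e[STREAM_HEADERS[[s]][-1]]
        as.data.frame(
          c(list(patient_id = b$patient_id),
            lapply(e, function(v) if (is.null(v)) NA else v)),
          stringsAsFactors = FALSE)
      }))
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      df <- as.data.frame(
        setNames(rep(list(character()), length(STREAM_HEADERS[[s]])),
                 STREAM_HEADERS[[s]]), stringsAsFactors = FALSE)
    }
    df[] <- lapply(df, as.character)
    tcol <- if (s == "medications") "start_date" else "timestamp"
    df[[tcol]] <- parse_date_col(df[[tcol]], path, tcol)
    if (s %in% c("measurements", "labs")) {
      df$value <- parse_num_col(df$value, path, "value")
    }
    if (s == "medications") df$active <- parse_logical_value(df$active)
    df
  })
  streams
}

#' Write patient records as raw stream files
#'
#' Serializes records back to the on-disk dialects read by
#' [extract_streams()]. Output is deterministic: rows ordered by patient
#' id, then timestamp, then code.
#'
#' @param records List of `patient_record` objects.
#' @param path For dialect `"a"`, the output directory (created if needed);
#'   for dialect `"b"`, the output JSON file path.
#' @param dialect `"a"` or `"b"`.
#' @return `path`, invisibly.
#' @export
write_streams <- function(records, path, dialect = c("a", "b")) {
  dialect <- match.arg(dialect)
  records <- records[order(vapply(records, `[[`, "", "patient_id"))]
  if (dialect == "a") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (s in names(STREAM_HEADERS)) {
      df <- do.call(rbind, lapply(records, function(r) {
        d <- r[[s]]
        d$recognized <- NULL
        if (!nrow(d)) return(NULL)
        cbind(patient_id = r$patient_id, d, stringsAsFactors = FALSE)
      }))
      if (is.null(df)) {
        df <- as.data.frame(
          setNames(rep(list(character()), length(STREAM_HEADERS[[s]])),
                   STREAM_HEADERS[[s]]), stringsAsFactors = FALSE)
      }
      ord <- do.call(order, unname(df[intersect(
        c("patient_id",
          if (s == "medications") "start_date" else "timestamp",
          setdiff(names(df), "patient_id")), names(df))]))
      df <- df[ord, STREAM_HEADERS[[s]], drop = FALSE]
      write.csv(df, file.path(path, paste0(s, ".csv")), row.names = FALSE,
                quote = TRUE)
    }
  } else {
    bundles <- lapply(records, function(r) {
      streams <- lapply(setNames(nm = names(STREAM_HEADERS)), function(s) {
        d <- r[[s]]
        d$recognized <- NULL
        d[] <- lapply(d, as.character)
        unname(apply(d, 1L, as.list))
      })
      c(list(patient_id = r$patient_id), streams)
    })
    jsonlite::write_json(unname(bundles), path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
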