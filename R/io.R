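## CSV / JSON surfaces. The CSV schemas are exactly the column sets of
## patient_columns()/followup_columns(): header mandatory, UTF-8, booleans
## 0/1, enums lowercase tokens, empty cell = missing. Parsing is strict:
## unknown columns and malformed cells are errors with row numbers, never
## silently dropped or defaulted.

parse_typed_csv <- function(path, columns, what) {
  if (!file.exists(path)) abort_validation(paste0(what, " file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(names(columns), names(raw))
  if (length(missing)) {
    abort_validation(paste0(what, ": missing column(s): ", paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(raw), names(columns))
  if (length(unknown)) {
    abort_validation(paste0(what, ": unknown column(s): ", paste(unknown, collapse = ", ")))
  }
  out <- raw[names(columns)]
  for (nm in names(columns)) {
    v <- out[[nm]]
    v[!is.na(v) & v == ""] <- NA_character_
    out[[nm]] <- switch(
      columns[[nm]],
      character = v,
      numeric = {
        num <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & is.na(num))
        if (length(bad)) {
          abort_validation(paste0(what, ": non-numeric value '", v[bad[1]],
                                  "' in column ", nm, ", line ", bad[1] + 1))
        }
        num
      },
      logical = {
        ok <- is.na(v) | v %in% c("0", "1")
        if (!all(ok)) {
          bad <- which(!ok)[1]
          abort_validation(paste0(what, ": boolean column ", nm,
                                  " must be 0/1, got '", v[bad],
                                  "' at line ", bad + 1))
        }
        v == "1"
      }
    )
  }
  out
}

#' Read and validate patient presentations from CSV
#'
#' @param path CSV file following the [patient_columns()] schema.
#' @param standards Threshold registry for eligibility checks.
#' @return Validated patient tibble.
#' @export
read_patients <- function(path, standards = reference_standards()) {
  validate_patients(parse_typed_csv(path, patient_columns(), "patients"),
                    as_standards(standards))
}

#' Read and validate follow-up observations from CSV
#'
#' @param path CSV file following the [followup_columns()] schema.
#' @return Validated follow-up tibble.
#' @export
read_followups <- function(path) {
  validate_followups(parse_typed_csv(path, followup_columns(), "followups"))
}

typed_to_csv <- function(data, columns, path) {
  out <- data[names(columns)]
  for (nm in names(columns)) {
    if (columns[[nm]] == "logical") out[[nm]] <- as.integer(out[[nm]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write patients / follow-ups in the canonical CSV schema
#'
#' Inverse of [read_patients()] / [read_followups()]; a write-read round trip
#' reproduces the records exactly.
#'
#' @param data Validated tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_patients <- function(data, path) {
  typed_to_csv(check_schema(tibble::as_tibble(data), patient_columns(), "patients"),
               patient_columns(), path)
}

#' @rdname write_patients
#' @export
write_followups <- function(data, path) {
  typed_to_csv(check_schema(tibble::as_tibble(data), followup_columns(), "followups"),
               followup_columns(), path)
}

#' Write an analysis report as versioned JSON
#'
#' @param report A data frame (e.g. the effect-estimate table of a
#'   [simulate_trial()] result) or a named list.
#' @param path Output path.
#' @param schema_version Schema tag written alongside the payload.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, schema_version = "1.0") {
  payload <- list(schema_version = schema_version, report = report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
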