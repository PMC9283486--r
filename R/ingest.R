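# Reading visit records, cohort filtering, and first-occurrence disease paths.

#' Read visit-level diagnosis records
#'
#' Reads a long-format delimited file (comma or tab, auto-detected by
#' `data.table::fread`) with one diagnosis event per row. Rows whose date
#' does not parse or whose code is empty are rejected, counted and reported
#' via a message, never silently dropped.
#'
#' @param source path to a delimited file, or a `data.frame` already in
#'   memory.
#' @param columns named character vector mapping the roles `patient_id`,
#'   `visit_date`, `code` to column names in the source.
#' @return `data.table` with columns `patient_id` (character), `visit_date`
#'   (`Date`), `code` (character); attribute `"n_rejected"` counts rejected
#'   rows.
#' @export
parse_records <- function(source,
                          columns = c(patient_id = "patient_id",
                                      visit_date = "visit_date",
                                      code = "icd9")) {
  stopifnot(all(c("patient_id", "visit_date", "code") %in% names(columns)))
  if (is.character(source)) {
    if (!file.exists(source)) stop("cannot read visit records: ", source)
    raw <- data.table::fread(source, colClasses = "character")
  } else {
    raw <- data.table::as.data.table(source)
    for (cl in intersect(unname(columns), names(raw))) {
      data.table::set(raw, j = cl, value = as.character(raw[[cl]]))
    }
  }
  if (nrow(raw) == 0L) {
    out <- data.table::data.table(patient_id = character(), visit_date = as.Date(character()),
                                  code = character())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.table::data.table(
    patient_id = raw[[columns[["patient_id"]]]],
    visit_date = as.Date(raw[[columns[["visit_date"]]]], format = "%Y-%m-%d"),
    code = trimws(raw[[columns[["code"]]]])
  )
  bad <- is.na(out$visit_date) | is.na(out$patient_id) | out$code == "" | is.na(out$code)
  if (any(bad)) {
    message(sprintf("parse_records: rejected %d malformed row(s) of %d", sum(bad), nrow(out)))
    out <- out[!bad]
  }
  attr(out, "n_rejected") <- sum(bad)
  out[]
}

#' Read the patient metadata table
#'
#' @param source path or data.frame with columns `patient_id`, `birth_date`,
#'   `death_date`, `sex` (values `male`/`female`/`unknown`; empty means
#'   unknown). Dates ISO-8601; empty strings become `NA`.
#' @return keyed `data.table`, one row per patient.
#' @export
parse_patients <- function(source) {
  raw <- if (is.character(source)) {
    data.table::fread(source, colClasses = "character")
  } else data.table::as.data.table(source)
  need <- c("patient_id", "birth_date", "death_date", "sex")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.table::data.table(
    patient_id = as.character(raw$patient_id),
    birth_date = as.Date(ifelse(as.character(raw$birth_date) == "", NA, as.character(raw$birth_date))),
    death_date = as.Date(ifelse(as.character(raw$death_date) == "", NA, as.character(raw$death_date))),
    sex = tolower(as.character(raw$sex))
  )
  out[is.na(sex) | !(sex %in% c("male", "female")), sex := "unknown"]
  bad <- !is.na(out$birth_date) & !is.na(out$death_date) & out$death_date < out$birth_date
  if (any(bad)) stop("death_date before birth_date for patient(s): ",
                     paste(out$patient_id[bad], collapse = ", "))
  data.table::setkey(out, patient_id)
  out[]
}

#' Apply the cohort filters
#'
#' Keeps records of patients passing the sex filter and at most `max_age`
#' years old at `reference_date`. Patients with no birth date are retained
#' (the age filter is inapplicable); patients with unknown sex are excluded
#' while a sex filter is active.
#'
#' @param records visit records from [parse_records()].
#' @param meta patient metadata from [parse_patients()].
#' @param max_age maximum age in whole years at `reference_date`.
#' @param reference_date date at which age is evaluated.
#' @param sex_filter `"male"`, `"female"` or `NULL` (no sex filter).
#' @return the subset of `records`; attribute `"n_patients_removed"`.
#' @export
filter_cohort <- function(records, meta, max_age = 99,
                          reference_date = as.Date("2018-10-01"),
                          sex_filter = "male") {
  records <- data.table::as.data.table(records)
  meta <- data.table::as.data.table(meta)
  keep <- meta[, .(patient_id, birth_date, sex)]
  # age in completed years at the reference date
  age <- floor(as.numeric(reference_date - keep$birth_date) / 365.25)
  ok_age <- is.na(keep$birth_date) | age <= max_age
  ok_sex <- if (is.null(sex_filter)) rep(TRUE, nrow(keep)) else keep$sex == sex_filter
  kept_ids <- keep$patient_id[ok_age & ok_sex]
  # patients absent from meta: no attributes known; retained unless a sex
  # filter is active (sex unknown => excluded, mirroring the unknown-sex rule)
  unmet <- setdiff(unique(records$patient_id), meta$patient_id)
  if (is.null(sex_filter)) kept_ids <- c(kept_ids, unmet)
  out <- records[patient_id %in% kept_ids]
  attr(out, "n_patients_removed") <-
    length(unique(records$patient_id)) - length(unique(out$patient_id))
  out[]
}

#' Build per-patient first-occurrence disease paths
#'
#' Truncates codes to 3 digits, drops V/E supplementary codes, and keeps for
#' each patient the earliest date of each distinct 3-digit code. Codes first
#' seen on the same date share a bucket; duplicate same-day rows of one code
#' collapse to one event.
#'
#' @param records cohort-filtered visit records.
#' @return keyed `data.table` with columns `patient_id`, `date`, `code`
#'   (one row per patient x first-occurring 3-digit code) and `bucket`, the
#'   1-based rank of the date within the patient's path. Attributes
#'   `"n_excluded_ve"` and `"n_invalid"` report dropped rows.
#' @export
extract_paths <- function(records) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    out <- data.table::data.table(patient_id = character(), date = as.Date(character()),
                                  code = character(), bucket = integer())
    attr(out, "n_excluded_ve") <- 0L
    attr(out, "n_invalid") <- 0L
    return(out)
  }
  code3 <- suppressWarnings(truncate_icd9(dt$code))
  n_invalid <- attr(code3, "n_invalid")
  n_ve <- sum(is.na(code3)) - n_invalid
  dt <- dt[!is.na(code3)]
  dt[, code := code3[!is.na(code3)]]
  paths <- dt[, .(date = min(visit_date)), by = .(patient_id, code)]
  data.table::setorder(paths, patient_id, date, code)
  paths[, bucket := data.table::frank(date, ties.method = "dense"), by = patient_id]
  data.table::setcolorder(paths, c("patient_id", "date", "code", "bucket"))
  data.table::setkey(paths, patient_id, date, code)
  attr(paths, "n_excluded_ve") <- n_ve
  attr(paths, "n_invalid") <- n_invalid
  paths[]
}

#' Write paths to a TSV for inspection
#'
#' One row per (patient, first-occurrence code), with the bucket rank.
#' @param paths from [extract_paths()].
#' @param file output path.
#' @export
write_paths <- function(paths, file) {
  out <- data.table::as.data.table(paths)[, .(patient_id, rank = bucket, date, code)]
  data.table::fwrite(out, file, sep = "\t")
  invisible(file)
}
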