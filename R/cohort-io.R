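#' Assemble a cohort from patient and event tables
#'
#' A cohort bundles per-patient metadata (birth date, end of data, cancer
#' diagnosis date if any) with the ordered diagnosis events. Events are
#' truncated to level-3 codes, sorted stably by date within patient (same-day
#' codes keep their input order), and validated against the patient dates.
#'
#' @param patients data.frame with columns `patient_id`, `birth_date`, `sex`
#'   (optional, may be NA), `end_of_data`, `cancer_date` (NA for controls).
#' @param events data.frame with columns `patient_id`, `date`, `code`,
#'   `system`.
#' @return an object of class `trajrisk_cohort`: a list with `data.table`s
#'   `patients` and `events`.
#' @export
as_cohort <- function(patients, events) {
  patients <- as.data.table(patients)
  events <- as.data.table(events)
  need_p <- c("patient_id", "birth_date", "end_of_data", "cancer_date")
  if (!all(need_p %in% names(patients))) {
    stop("patients table must have columns ", paste(need_p, collapse = ", "))
  }
  if (!"sex" %in% names(patients)) patients[, sex := NA_character_]
  need_e <- c("patient_id", "date", "code", "system")
  if (!all(need_e %in% names(events))) {
    stop("events table must have columns ", paste(need_e, collapse = ", "))
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id in patients table")
  }
  for (col in c("birth_date", "end_of_data", "cancer_date")) {
    set(patients, j = col, value = as.Date(patients[[col]]))
  }
  set(events, j = "date", value = as.Date(events$date))
  events[, code := truncate_code(code)]
  events[, system := as.character(system)]

  unknown <- setdiff(events$patient_id, patients$patient_id)
  if (length(unknown)) {
    stop("events reference unknown patients: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  # stable sort: same-day events keep input order
  setkey(patients, patient_id)
  events <- events[order(patient_id, date)]

  chk <- merge(events, patients[, .(patient_id, birth_date, end_of_data)],
               by = "patient_id", sort = FALSE)
  bad <- chk$date < chk$birth_date | chk$date > chk$end_of_data
  if (any(bad)) {
    stop("events outside [birth_date, end_of_data] for patients: ",
         paste(utils::head(unique(chk$patient_id[bad]), 5L), collapse = ", "))
  }
  bad_cd <- !is.na(patients$cancer_date) &
    patients$cancer_date > patients$end_of_data
  if (any(bad_cd)) {
    stop("cancer_date after end_of_data for patients: ",
         paste(utils::head(patients$patient_id[bad_cd], 5L), collapse = ", "))
  }
  structure(list(patients = patients, events = events),
            class = "trajrisk_cohort")
}

#' @export
print.trajrisk_cohort <- function(x, ...) {
  n_case <- sum(!is.na(x$patients$cancer_date))
  cat("<trajrisk_cohort> ", nrow(x$patients), " patients (", n_case,
      " cancer cases), ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

parse_date_column <- function(x, col, path) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & nzchar(as.character(x)) & is.na(d))
  if (length(bad)) {
    stop(sprintf("%s: malformed %s on line %s (value '%s')",
                 path, col, bad[1L] + 1L, x[bad[1L]])) # +1 for header row
  }
  d
}

#' Read and write delimited event / patient files
#'
#' Plain-text interchange format: tab-separated (configurable), header row
#' required, ISO-8601 dates. `read_*` validates dates and reports the first
#' offending line; `write_*` emits stable row order so that seeded generation
#' is byte-reproducible. Empty `cancer_date` marks a control.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `read_event_file` returns a `data.table` with columns
#'   `patient_id`, `date`, `code`, `system`; `read_patient_file` one with
#'   `patient_id`, `birth_date`, `sex`, `end_of_data`, `cancer_date`.
#' @name event_files
#' @export
read_event_file <- function(path, sep = "\t") {
  dt <- fread(path, sep = sep, colClasses = "character")
  need <- c("patient_id", "date", "code", "system")
  if (!all(need %in% names(dt))) {
    stop(path, ": event file must have columns ", paste(need, collapse = ", "))
  }
  dt[, date := parse_date_column(date, "date", path)]
  if (anyNA(dt$date)) {
    stop(path, ": missing date on line ", which(is.na(dt$date))[1L] + 1L)
  }
  dt[]
}

#' @rdname event_files
#' @param events,patients tables as returned by the corresponding readers.
#' @export
write_event_file <- function(events, path, sep = "\t") {
  out <- as.data.table(events)[, .(patient_id, date = format(date, "%Y-%m-%d"),
                                   code, system)]
  fwrite(out, path, sep = sep)
  invisible(path)
}

#' @rdname event_files
#' @export
read_patient_file <- function(path, sep = "\t") {
  dt <- fread(path, sep = sep, colClasses = "character")
  need <- c("patient_id", "birth_date", "end_of_data", "cancer_date")
  if (!all(need %in% names(dt))) {
    stop(path, ": patient file must have columns ",
         paste(need, collapse = ", "))
  }
  if (!"sex" %in% names(dt)) dt[, sex := NA_character_]
  for (col in c("birth_date", "end_of_data", "cancer_date")) {
    set(dt, j = col, value = parse_date_column(dt[[col]], col, path))
  }
  dt[, .(patient_id, birth_date, sex, end_of_data, cancer_date)]
}

#' @rdname event_files
#' @export
write_patient_file <- function(patients, path, sep = "\t") {
  fmt <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  out <- as.data.table(patients)[, .(
    patient_id, birth_date = fmt(birth_date), sex,
    end_of_data = fmt(end_of_data), cancer_date = fmt(cancer_date))]
  fwrite(out, path, sep = sep)
  invisible(path)
}

#' Read a cohort from an event file and a patient file
#'
#' @param events_path,patients_path file paths.
#' @inheritParams event_files
#' @return a `trajrisk_cohort`.
#' @export
read_cohort <- function(events_path, patients_path, sep = "\t") {
  as_cohort(read_patient_file(patients_path, sep),
            read_event_file(events_path, sep))
}
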