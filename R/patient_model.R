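# Patient / prescription data model, concomitance semantics, and JSON Lines
# I/O. Prescriptions live on half-open date intervals [start, end): a drug
# is concomitant with a new prescription iff it is active on the prescribing
# date.

#' Construct a prescription
#'
#' @param rx_id identifier, unique within a patient record
#' @param product_id formulary product id
#' @param daily_dose prescribed daily dose (optional; NA when unknown)
#' @param dose_unit unit of daily_dose, e.g. "mg"
#' @param start_date,end_date ISO dates; a missing end date means open-ended
#' @param status "active" or "ended"; only consulted when end_date is absent
#' @export
prescription <- function(rx_id, product_id, daily_dose = NA_real_,
                         dose_unit = NA_character_, start_date,
                         end_date = NULL, status = "active") {
  start_date <- as_iso_date(start_date, "start_date")
  if (!is.null(end_date) && !is.na(end_date[1])) {
    end_date <- as_iso_date(end_date, "end_date")
    if (end_date < start_date)
      abort_fmt("prescription '%s': end_date precedes start_date", rx_id)
  } else end_date <- NULL
  if (!is.na(daily_dose)) {
    if (!is_scalar_number(daily_dose) || daily_dose < 0)
      abort_fmt("prescription '%s': daily_dose must be a non-negative number", rx_id)
  }
  if (!status %in% c("active", "ended"))
    abort_fmt("prescription '%s': status must be 'active' or 'ended'", rx_id)
  structure(list(rx_id = rx_id, product_id = product_id,
                 daily_dose = as.numeric(daily_dose), dose_unit = dose_unit,
                 start_date = start_date, end_date = end_date, status = status),
            class = "prescription")
}

#' Construct a clinical measurement (e.g. eGFR in mL/min/1.73m2, potassium
#' in mmol/L)
#' @export
clinical_measurement <- function(label, value, date) {
  if (!nzchar(label)) abort_fmt("measurement label must be non-empty")
  if (!is_scalar_number(value)) abort_fmt("measurement '%s': value must be finite", label)
  structure(list(label = label, value = as.numeric(value),
                 date = as_iso_date(date, "measurement date")),
            class = "clinical_measurement")
}

#' Construct a hypersensitivity / adverse-drug-reaction history record
#'
#' `target` is either a drug-group id (cross-reactivity group) or an
#' ingredient id; it is resolved against the rulebase at evaluation time.
#' @export
sensitivity_record <- function(kind, target, date) {
  if (!kind %in% c("suspected_hypersensitivity", "adverse_drug_reaction"))
    abort_fmt("sensitivity kind must be 'suspected_hypersensitivity' or 'adverse_drug_reaction'")
  if (!nzchar(target)) abort_fmt("sensitivity target must be non-empty")
  structure(list(kind = kind, target = target,
                 date = as_iso_date(date, "sensitivity date")),
            class = "sensitivity_record")
}

#' Construct a patient record
#'
#' @param patient_id unique identifier
#' @param birth_date ISO date
#' @param sex "F" or "M"
#' @param pregnant logical; TRUE only allowed when sex == "F"
#' @param prescriptions list of [prescription()]
#' @param problems list of list(code, onset): ICD-10 coded active problems
#' @param measurements list of [clinical_measurement()]
#' @param sensitivities list of [sensitivity_record()]
#' @export
patient_record <- function(patient_id, birth_date, sex, pregnant = FALSE,
                           prescriptions = list(), problems = list(),
                           measurements = list(), sensitivities = list()) {
  if (!nzchar(patient_id)) abort_fmt("patient record needs a non-empty patient_id")
  if (!sex %in% c("F", "M")) abort_fmt("patient '%s': sex must be 'F' or 'M'", patient_id)
  if (!is.logical(pregnant) || length(pregnant) != 1L || is.na(pregnant))
    abort_fmt("patient '%s': pregnant must be TRUE or FALSE", patient_id)
  if (pregnant && sex != "F")
    abort_fmt("patient '%s': pregnant = TRUE requires sex = 'F'", patient_id)
  problems <- lapply(problems, function(p) {
    list(code = parse_icd10(p$code),
         onset = if (!is.null(p$onset)) as_iso_date(p$onset, "problem onset") else NULL)
  })
  rx_ids <- vapply(prescriptions, `[[`, character(1), "rx_id")
  if (anyDuplicated(rx_ids))
    abort_fmt("patient '%s': duplicate rx_id within record", patient_id)
  structure(list(patient_id = patient_id,
                 birth_date = as_iso_date(birth_date, "birth_date"),
                 sex = sex, pregnant = pregnant,
                 prescriptions = prescriptions, problems = problems,
                 measurements = measurements, sensitivities = sensitivities),
            class = "patient_record")
}

#' Completed years of age at a date (birthday-anniversary rule)
#' @export
age_at <- function(patient, date) {
  stopifnot(inherits(patient, "patient_record"))
  d <- as_iso_date(date)
  b <- patient$birth_date
  if (d < b) abort_fmt("patient '%s': date %s precedes birth_date %s",
                       patient$patient_id, format(d), format(b))
  db <- as.POSIXlt(b); dd <- as.POSIXlt(d)
  age <- dd$year - db$year
  before_anniversary <- dd$mon < db$mon || (dd$mon == db$mon && dd$mday < db$mday)
  as.integer(age - before_anniversary)
}

#' Prescriptions active on a date
#'
#' Active means start_date <= date < end_date; a prescription with no end
#' date is open-ended unless its status is "ended". Result is ordered by
#' start date, then rx_id.
#' @export
active_prescriptions <- function(patient, date) {
  stopifnot(inherits(patient, "patient_record"))
  d <- as_iso_date(date)
  act <- Filter(function(rx) {
    if (rx$start_date > d) return(FALSE)
    if (!is.null(rx$end_date)) return(d < rx$end_date)
    rx$status != "ended"
  }, patient$prescriptions)
  ord <- order(as.Date(vapply(act, function(rx) format(rx$start_date), character(1))),
               vapply(act, `[[`, character(1), "rx_id"))
  act[ord]
}

#' Most recent measurement with a label within a staleness window
#'
#' Returns the latest measurement dated in (date - max_age_days, date], or
#' NULL when none exists. Rules relying on an absent measurement silently do
#' not fire.
#' @export
latest_measurement <- function(patient, label, date, max_age_days = 365L) {
  stopifnot(inherits(patient, "patient_record"))
  if (!is_scalar_number(max_age_days) || max_age_days <= 0)
    abort_fmt("max_age_days must be > 0")
  d <- as_iso_date(date)
  hits <- Filter(function(m) m$label == label &&
                   m$date <= d && m$date > d - max_age_days,
                 patient$measurements)
  if (length(hits) == 0L) return(NULL)
  dates <- as.Date(vapply(hits, function(m) format(m$date), character(1)))
  hits[[which.max(dates)]]
}

# ---- JSON Lines I/O ----------------------------------------------------

patient_to_list <- function(p) {
  list(
    patient_id = p$patient_id,
    birth_date = format(p$birth_date),
    sex = p$sex,
    pregnant = p$pregnant,
    prescriptions = lapply(p$prescriptions, function(rx) {
      out <- list(rx_id = rx$rx_id, product_id = rx$product_id,
                  start_date = format(rx$start_date), status = rx$status)
      if (!is.na(rx$daily_dose)) {
        out$daily_dose <- rx$daily_dose
        out$dose_unit <- rx$dose_unit
      }
      if (!is.null(rx$end_date)) out$end_date <- format(rx$end_date)
      out
    }),
    problems = lapply(p$problems, function(pr) {
      out <- list(code = pr$code)
      if (!is.null(pr$onset)) out$onset <- format(pr$onset)
      out
    }),
    measurements = lapply(p$measurements, function(m)
      list(label = m$label, value = m$value, date = format(m$date))),
    sensitivities = lapply(p$sensitivities, function(s)
      list(kind = s$kind, target = s$target, date = format(s$date)))
  )
}

patient_from_list <- function(x, line = NA_integer_) {
  ctx <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  need <- c("patient_id", "birth_date", "sex")
  for (f in need) if (is.null(x[[f]]))
    abort_fmt("patient record%s: missing field '%s'", ctx, f)
  tryCatch(
    patient_record(
      patient_id = x$patient_id, birth_date = x$birth_date, sex = x$sex,
      pregnant = isTRUE(x$pregnant),
      prescriptions = lapply(x$prescriptions %||% list(), function(rx)
        prescription(rx$rx_id, rx$product_id,
                     daily_dose = rx$daily_dose %||% NA_real_,
                     dose_unit = rx$dose_unit %||% NA_character_,
                     start_date = rx$start_date, end_date = rx$end_date,
                     status = rx$status %||% "active")),
      problems = x$problems %||% list(),
      measurements = lapply(x$measurements %||% list(), function(m)
        clinical_measurement(m$label, m$value, m$date)),
      sensitivities = lapply(x$sensitivities %||% list(), function(s)
        sensitivity_record(s$kind, s$target, s$date))),
    error = function(e) abort_fmt("patient record%s: %s", ctx, conditionMessage(e)))
}

#' Read patient records from a JSON Lines file
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) abort_fmt("%s line %d: invalid JSON", path, i))
    p <- patient_from_list(x, line = i)
    if (p$patient_id %in% seen)
      abort_fmt("%s line %d: duplicate patient_id '%s'", path, i, p$patient_id)
    seen <- c(seen, p$patient_id)
    out[[i]] <- p
  }
  names(out) <- seen
  out
}

#' Write patient records as JSON Lines (inverse of [read_patients()])
#' @export
write_patients <- function(records, path) {
  lines <- vapply(records, function(p) {
    stopifnot(inherits(p, "patient_record"))
    jsonlite::toJSON(patient_to_list(p), auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read candidate prescribing episodes from JSON Lines
#'
#' Each line: patient_id, product_id, date, optional daily_dose/dose_unit,
#' optional event_id (assigned sequentially when absent).
#' @export
read_episodes <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) abort_fmt("%s line %d: invalid JSON", path, i))
    for (f in c("patient_id", "product_id", "date")) if (is.null(x[[f]]))
      abort_fmt("%s line %d: missing field '%s'", path, i, f)
    list(event_id = x$event_id %||% sprintf("E%06d", i),
         patient_id = x$patient_id, product_id = x$product_id,
         daily_dose = x$daily_dose %||% NA_real_,
         dose_unit = x$dose_unit %||% NA_character_,
         date = format(as_iso_date(x$date, "episode date")))
  })
}

#' Write prescribing episodes as JSON Lines
#' @export
write_episodes <- function(episodes, path) {
  lines <- vapply(episodes, function(e) {
    out <- list(event_id = e$event_id, patient_id = e$patient_id,
                product_id = e$product_id, date = e$date)
    if (!is.na(e$daily_dose %||% NA_real_)) {
      out$daily_dose <- e$daily_dose
      out$dose_unit <- e$dose_unit
    }
    jsonlite::toJSON(out, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
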