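# Episode logging and alert-acceptance semantics. An alert is "accepted"
# when the medicine that generated it was NOT prescribed; issuing the drug
# with a dose reduction or a follow-up order (outcome
# "prescribed_modified") does not count as acceptance, which is a known
# undercount the simulator can quantify.

EPISODE_OUTCOMES <- c("prescribed", "not_prescribed", "prescribed_modified")

#' Record one prescribing episode as an immutable audit event
#'
#' @param candidate_product formulary product id of the evaluated candidate
#' @param screen the [assemble_screen()] / [evaluate()] output
#' @param outcome one of "prescribed", "not_prescribed",
#'   "prescribed_modified"
#' @param timestamp ISO datetime (or date) of the episode
#' @param patient_id patient the episode belongs to
#' @param event_id unique id; derived from timestamp/patient/product when
#'   omitted
#' @export
record_episode <- function(candidate_product, screen, outcome, timestamp,
                           patient_id, event_id = NULL) {
  if (!outcome %in% EPISODE_OUTCOMES)
    abort_fmt("unknown outcome '%s' (expected one of %s)", outcome,
              paste(EPISODE_OUTCOMES, collapse = ", "))
  ts <- as.character(timestamp)
  year <- as.integer(substr(ts, 1L, 4L))
  if (is.na(year)) abort_fmt("timestamp '%s' does not start with a year", ts)
  structure(list(
    event_id = event_id %||% paste(ts, patient_id, candidate_product, sep = "|"),
    timestamp = ts, patient_id = patient_id,
    candidate_product = candidate_product, year = year,
    alerts = unclass(screen), outcome = outcome),
    class = "alert_event")
}

#' Was the alert of an episode accepted?
#'
#' Acceptance is a pure function of the episode outcome and is uniform
#' across all alerts of the episode (the tool observes a single prescribing
#' decision): TRUE iff the candidate was not prescribed. An episode without
#' alerts has no acceptance and is a domain error.
#' @export
is_accepted <- function(event) {
  stopifnot(inherits(event, "alert_event"))
  if (length(event$alerts) == 0L)
    abort_fmt("event '%s' raised no alert; acceptance is undefined", event$event_id)
  identical(event$outcome, "not_prescribed")
}

alert_to_list <- function(a) {
  list(rule_id = a$rule_id, checker = a$checker, family = a$family,
       severity = a$severity, candidate_product = a$candidate_product,
       conflicting_type = a$conflicting_type, conflicting_id = a$conflicting_id,
       risk_text = a$risk_text, alternatives = as.list(a$alternatives),
       subtype = if (is.na(a$subtype)) NULL else a$subtype)
}

alert_from_list <- function(x) {
  new_alert(x$rule_id, x$checker, x$severity, x$candidate_product,
            x$conflicting_type, x$conflicting_id, x$risk_text,
            alternatives = as.character(unlist(x$alternatives %||% list())),
            subtype = x$subtype %||% NA_character_)
}

AUDIT_SCHEMA <- list(schema = "mrp-audit", version = 1L)

#' Write an audit log as JSON Lines (schema header + one event per line)
#' @export
write_audit <- function(events, path) {
  header <- jsonlite::toJSON(AUDIT_SCHEMA, auto_unbox = TRUE)
  lines <- vapply(events, function(e) {
    stopifnot(inherits(e, "alert_event"))
    jsonlite::toJSON(list(
      event_id = e$event_id, timestamp = e$timestamp,
      patient_id = e$patient_id, candidate_product = e$candidate_product,
      year = e$year, alerts = lapply(e$alerts, alert_to_list),
      outcome = e$outcome), auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read an audit log written by [write_audit()]
#'
#' Events are returned sorted by timestamp (then event id). Malformed lines
#' are reported with their line number.
#' @export
read_audit <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_fmt("%s: empty audit log (schema header missing)", path)
  header <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = FALSE),
                     error = function(e) abort_fmt("%s line 1: invalid JSON header", path))
  if (!identical(header$schema, "mrp-audit"))
    abort_fmt("%s line 1: not an audit log (schema header missing)", path)
  events <- lapply(seq_along(lines[-1]), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i + 1L], simplifyVector = FALSE),
                  error = function(e) abort_fmt("%s line %d: invalid JSON", path, i + 1L))
    for (f in c("event_id", "timestamp", "patient_id", "candidate_product", "outcome"))
      if (is.null(x[[f]])) abort_fmt("%s line %d: missing field '%s'", path, i + 1L, f)
    e <- record_episode(x$candidate_product,
                        structure(lapply(x$alerts %||% list(), alert_from_list),
                                  class = "alert_screen"),
                        x$outcome, x$timestamp, x$patient_id, event_id = x$event_id)
    if (!is.null(x$year) && as.integer(x$year) != e$year)
      abort_fmt("%s line %d: year %s inconsistent with timestamp %s",
                path, i + 1L, x$year, x$timestamp)
    e
  })
  ord <- order(vapply(events, `[[`, character(1), "timestamp"),
               vapply(events, `[[`, character(1), "event_id"))
  events[ord]
}
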