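#' Construct a clinical event log
#'
#' An event log holds the time-ordered clinical events of a set of patients
#' (one trace per patient) together with trace-level patient attributes such
#' as symptom-onset and hospital-arrival times. Events are sorted ascending
#' by timestamp; ties are broken by lifecycle (`start` before `complete`),
#' then by activity code, then by input order, so sorting is stable and
#' deterministic.
#'
#' @param events Data frame with columns `case_id`, `code`, `name`,
#'   `lifecycle` (`"start"` or `"complete"`), `timestamp` (POSIXct), plus any
#'   event-attribute columns (e.g. `dose_mg`, `stage`).
#' @param patients Optional data frame keyed by `case_id` with patient
#'   attributes (`onset_time`, `arrival_time`, `neurology_arrival_time`, ...).
#'   Defaults to the distinct case ids of `events`.
#' @param metadata Free-form list describing the log's provenance.
#' @return A `careflow_log` object.
#' @export
event_log <- function(events, patients = NULL, metadata = list()) {
  ev <- as_tibble(events)
  req <- c("case_id", "code", "name", "lifecycle", "timestamp")
  missing_cols <- setdiff(req, names(ev))
  if (length(missing_cols) > 0L) {
    abort(sprintf("events missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  ev$case_id <- as.character(ev$case_id)
  ev$code <- as.character(ev$code)
  ev$name <- as.character(ev$name)
  ev$lifecycle <- as.character(ev$lifecycle)
  bad_lc <- !ev$lifecycle %in% c("start", "complete")
  if (any(bad_lc)) {
    abort(sprintf("invalid lifecycle value(s): %s",
                  paste(unique(ev$lifecycle[bad_lc]), collapse = ", ")))
  }
  if (!inherits(ev$timestamp, "POSIXct")) {
    abort("events$timestamp must be POSIXct")
  }
  if (anyNA(ev$timestamp)) {
    abort(sprintf("missing timestamp for case(s): %s",
                  paste(unique(ev$case_id[is.na(ev$timestamp)]), collapse = ", ")))
  }
  attr(ev$timestamp, "tzone") <- "UTC"
  ev <- sort_events(ev)
  if (is.null(patients)) {
    patients <- tibble(case_id = unique(ev$case_id))
  }
  patients <- as_tibble(patients)
  if (!"case_id" %in% names(patients)) abort("patients must have a case_id column")
  patients$case_id <- as.character(patients$case_id)
  if (anyDuplicated(patients$case_id)) {
    abort(sprintf("duplicate case_id(s) in patients: %s",
                  paste(unique(patients$case_id[duplicated(patients$case_id)]),
                        collapse = ", ")))
  }
  for (col in intersect(c("onset_time", "arrival_time", "neurology_arrival_time"),
                        names(patients))) {
    if (inherits(patients[[col]], "POSIXct")) attr(patients[[col]], "tzone") <- "UTC"
  }
  structure(list(events = ev, patients = patients, metadata = metadata),
            class = "careflow_log")
}

# canonical event order: time, then start before complete, then code, then
# original row order (stable)
sort_events <- function(ev) {
  o <- order(ev$timestamp,
             match(ev$lifecycle, c("start", "complete")),
             ev$code,
             seq_len(nrow(ev)))
  ev[o, , drop = FALSE]
}

#' @export
is_careflow_log <- function(x) inherits(x, "careflow_log")

#' @export
print.careflow_log <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<careflow_log> %d traces, %d events, %d activities\n",
              length(unique(ev$case_id)), nrow(ev), length(unique(ev$code))))
  if (nrow(ev) > 0L) {
    cat(sprintf("  time span: %s .. %s\n",
                format(min(ev$timestamp), "%Y-%m-%d %H:%M", tz = "UTC"),
                format(max(ev$timestamp), "%Y-%m-%d %H:%M", tz = "UTC")))
  }
  invisible(x)
}

#' Number of traces in a log
#' @param log A `careflow_log`.
#' @export
n_traces <- function(log) {
  stopifnot(is_careflow_log(log))
  nrow(log$patients)
}

#' Case identifiers of a log
#' @param log A `careflow_log`.
#' @export
case_ids <- function(log) {
  stopifnot(is_careflow_log(log))
  log$patients$case_id
}

#' Restrict a log to a subset of cases
#' @param log A `careflow_log`.
#' @param ids Character vector of case ids to keep.
#' @export
filter_cases <- function(log, ids) {
  stopifnot(is_careflow_log(log))
  log$events <- log$events[log$events$case_id %in% ids, , drop = FALSE]
  log$patients <- log$patients[log$patients$case_id %in% ids, , drop = FALSE]
  log
}

#' Codes and names of the three artificial milestone events
#'
#' Milestones derived from patient attributes rather than clinical orders:
#' symptom onset, arrival at the hospital and arrival at the neurology
#' department. They live under the reserved `C.A` branch of the ontology.
#'
#' @return Tibble with columns `attribute`, `code`, `name`.
#' @export
artificial_events <- function() {
  tibble(
    attribute = c("onset_time", "arrival_time", "neurology_arrival_time"),
    code = c("C.A.1", "C.A.2", "C.A.3"),
    name = c("Onset", "Arrive at hospital", "Arrive at neurology department")
  )
}

#' Default anchor activity (hospital arrival)
#' @return The activity code of the "Arrive at hospital" milestone.
#' @export
anchor_code <- function() "C.A.2"

#' Insert artificial milestone events into every trace
#'
#' Adds one `complete` event per available milestone timestamp (onset,
#' hospital arrival and, when recorded, neurology arrival) from the patient
#' attributes. Onset and arrival are required; traces lacking them should be
#' removed by the rule engine first. The operation is idempotent: milestones
#' already present in a trace are not duplicated.
#'
#' @param log A `careflow_log` whose patients carry `onset_time` and
#'   `arrival_time`.
#' @return The log with artificial events inserted in time order.
#' @export
add_artificial_events <- function(log) {
  stopifnot(is_careflow_log(log))
  pats <- log$patients
  art <- artificial_events()
  if (!all(c("onset_time", "arrival_time") %in% names(pats))) {
    abort("patients must carry onset_time and arrival_time; run the rule engine first")
  }
  miss <- is.na(pats$onset_time) | is.na(pats$arrival_time)
  if (any(miss)) {
    abort(sprintf("missing onset/arrival time for case(s): %s (rule 1 territory)",
                  paste(pats$case_id[miss], collapse = ", ")))
  }
  rows <- purrr::map_dfr(seq_len(nrow(art)), function(i) {
    attr_col <- art$attribute[i]
    if (!attr_col %in% names(pats)) return(NULL)
    ts <- pats[[attr_col]]
    keep <- !is.na(ts)
    tibble(case_id = pats$case_id[keep], code = art$code[i], name = art$name[i],
           lifecycle = "complete", timestamp = ts[keep])
  })
  if (nrow(rows) > 0L) {
    # idempotence: skip milestones a trace already carries
    have <- paste(log$events$case_id, log$events$code)
    rows <- rows[!paste(rows$case_id, rows$code) %in% have, , drop = FALSE]
  }
  if (nrow(rows) == 0L) return(log)
  ev <- bind_rows(log$events, rows)
  log$events <- sort_events(ev)
  log
}

# standard columns of the events table; everything else is an open attribute
event_core_cols <- function() c("case_id", "code", "name", "lifecycle", "timestamp")

# compare two logs for semantic equality (used by round-trip tests)
#' Test two event logs for equality
#'
#' Compares events (including attribute columns), patient attributes and
#' nothing else; metadata is ignored. Timestamps compare to the second.
#'
#' @param a,b `careflow_log` objects.
#' @export
logs_equal <- function(a, b) {
  stopifnot(is_careflow_log(a), is_careflow_log(b))
  ev_a <- a$events[, order(names(a$events))]
  ev_b <- b$events[, order(names(b$events))]
  p_a <- a$patients[order(a$patients$case_id), order(names(a$patients))]
  p_b <- b$patients[order(b$patients$case_id), order(names(b$patients))]
  isTRUE(all.equal(as.data.frame(ev_a), as.data.frame(ev_b),
                   check.attributes = FALSE)) &&
    isTRUE(all.equal(as.data.frame(p_a), as.data.frame(p_b),
                     check.attributes = FALSE))
}
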