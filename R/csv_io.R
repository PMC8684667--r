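# --- flat CSV event tables ---------------------------------------------------
#
# Header: case_id,code,name,lifecycle,timestamp + free attribute columns.
# ISO-8601 timestamps. A row with an empty lifecycle stands for an activity
# for which only one instant was recorded (e.g. nursing); it expands into a
# start and a complete event at the same timestamp, reflecting the
# convention that such activities start when they finish.

parse_iso_time <- function(x) {
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  has_sec <- grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$", x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  out[has_sec] <- as.POSIXct(x[has_sec], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  min_only <- !has_sec & grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}$", x)
  out[min_only] <- as.POSIXct(x[min_only], format = "%Y-%m-%d %H:%M", tz = "UTC")
  out
}

#' Read an event log from CSV
#'
#' @param events_path CSV with header
#'   `case_id,code,name,lifecycle,timestamp` plus optional attribute columns.
#'   `code` or `name` may be blank when the other resolves via `ontology`.
#' @param ontology Optional `ontology` used to resolve codes from names (and
#'   names from codes) and to reject unknown activities.
#' @param patients_path Optional sidecar CSV
#'   (`case_id,onset_time,arrival_time,neurology_arrival_time,...`).
#' @return A `careflow_log`.
#' @export
read_csv_log <- function(events_path, ontology = NULL, patients_path = NULL) {
  df <- read.csv(events_path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("case_id", "timestamp")
  if (!all(req %in% names(df))) {
    abort("event CSV must have at least case_id and timestamp columns")
  }
  if (!"code" %in% names(df)) df$code <- NA_character_
  if (!"name" %in% names(df)) df$name <- NA_character_
  if (!"lifecycle" %in% names(df)) df$lifecycle <- NA_character_
  ts <- parse_iso_time(as.character(df$timestamp))
  if (anyNA(ts)) {
    abort(sprintf("unparseable timestamp at row(s): %s",
                  paste(which(is.na(ts)), collapse = ", ")))
  }
  df$timestamp <- ts
  if (!is.null(ontology)) {
    need_code <- is.na(df$code)
    df$code[need_code] <- ontology$code[match(df$name[need_code], ontology$name)]
    bad <- which(is.na(df$code))
    if (length(bad) > 0L) {
      abort(sprintf("unknown activity at row(s) %s",
                    paste(bad, collapse = ", ")))
    }
    unknown <- !df$code %in% ontology$code
    if (any(unknown)) {
      abort(sprintf("unknown activity code(s): %s (row %s)",
                    paste(unique(df$code[unknown]), collapse = ", "),
                    paste(which(unknown), collapse = ", ")))
    }
    need_name <- is.na(df$name)
    df$name[need_name] <- ontology$name[match(df$code[need_name], ontology$code)]
  } else {
    if (anyNA(df$code)) {
      abort(sprintf("missing activity code at row(s): %s",
                    paste(which(is.na(df$code)), collapse = ", ")))
    }
    df$name[is.na(df$name)] <- df$code[is.na(df$name)]
  }
  # single-instant rows (no lifecycle) expand to paired start/complete events
  single <- is.na(df$lifecycle)
  if (any(single)) {
    dup <- df[single, , drop = FALSE]
    df$lifecycle[single] <- "start"
    dup$lifecycle <- "complete"
    df <- bind_rows(df, dup)
  }
  patients <- NULL
  if (!is.null(patients_path)) {
    pd <- read.csv(patients_path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
    for (col in setdiff(names(pd), "case_id")) {
      if (grepl("_time$", col)) pd[[col]] <- parse_iso_time(as.character(pd[[col]]))
    }
    patients <- as_tibble(pd)
  }
  event_log(as_tibble(df), patients, metadata = list(source = events_path))
}

#' Write an event log as CSV
#'
#' Writes the events table (ISO-8601 timestamps) and, when `patients_path`
#' is given, the patient-attribute sidecar.
#'
#' @param log A `careflow_log`.
#' @param events_path Output path for the events table.
#' @param patients_path Optional output path for patient attributes.
#' @return `events_path`, invisibly.
#' @export
write_csv_log <- function(log, events_path, patients_path = NULL) {
  stopifnot(is_careflow_log(log))
  ev <- log$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(ev, events_path, row.names = FALSE, na = "")
  if (!is.null(patients_path)) {
    pd <- log$patients
    for (col in names(pd)) {
      if (inherits(pd[[col]], "POSIXct")) {
        pd[[col]] <- format(pd[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
      }
    }
    write.csv(pd, patients_path, row.names = FALSE, na = "")
  }
  invisible(events_path)
}
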