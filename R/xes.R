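# --- XES (IEEE 1849) event-stream input/output ------------------------------
#
# Dialect: trace-level concept:name = case id; each event carries its display
# name in concept:name, its activity code in the custom string attribute
# activity:code, lifecycle:transition and time:timestamp. Patient attributes
# are trace-level attributes (dates for *_time columns). Readers tolerate
# logs without activity:code by matching names against an ontology.

xes_time_fmt <- "%Y-%m-%dT%H:%M:%S"

format_xes_time <- function(ts) {
  paste0(format(ts, xes_time_fmt, tz = "UTC"), "Z")
}

parse_xes_time <- function(x) {
  x <- sub("Z$", "", sub("\\+00:?00$", "", x))
  x <- sub("\\.[0-9]+$", "", x)  # fractional seconds dropped (minute data)
  out <- as.POSIXct(x, format = xes_time_fmt, tz = "UTC")
  out
}

# typed XES attribute node
xes_attr_node <- function(parent, key, value) {
  if (inherits(value, "POSIXct")) {
    xml2::xml_add_child(parent, "date", key = key, value = format_xes_time(value))
  } else if (is.logical(value)) {
    xml2::xml_add_child(parent, "boolean", key = key,
                        value = if (isTRUE(value)) "true" else "false")
  } else if (is.integer(value)) {
    xml2::xml_add_child(parent, "int", key = key, value = as.character(value))
  } else if (is.numeric(value)) {
    xml2::xml_add_child(parent, "float", key = key,
                        value = format(value, scientific = FALSE, trim = TRUE))
  } else {
    xml2::xml_add_child(parent, "string", key = key, value = as.character(value))
  }
  invisible(parent)
}

#' Write an event log as XES
#'
#' @param log A `careflow_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xes <- function(log, path) {
  stopifnot(is_careflow_log(log))
  doc <- xml2::xml_new_root("log", "xes.version" = "1.0",
                            "xes.features" = "nested-attributes")
  xml2::xml_add_child(doc, "extension", name = "Concept", prefix = "concept",
                      uri = "http://www.xes-standard.org/concept.xesext")
  xml2::xml_add_child(doc, "extension", name = "Time", prefix = "time",
                      uri = "http://www.xes-standard.org/time.xesext")
  xml2::xml_add_child(doc, "extension", name = "Lifecycle", prefix = "lifecycle",
                      uri = "http://www.xes-standard.org/lifecycle.xesext")
  attr_cols <- setdiff(names(log$events), event_core_cols())
  pat_cols <- setdiff(names(log$patients), "case_id")
  ev_by_case <- split(log$events, log$events$case_id)
  for (cid in log$patients$case_id) {
    tr <- xml2::xml_add_child(doc, "trace")
    xes_attr_node(tr, "concept:name", cid)
    prow <- log$patients[log$patients$case_id == cid, , drop = FALSE]
    for (col in pat_cols) {
      v <- prow[[col]][1]
      if (!is.na(v)) xes_attr_node(tr, col, v)
    }
    ev <- ev_by_case[[cid]]
    if (is.null(ev)) next
    for (i in seq_len(nrow(ev))) {
      e <- xml2::xml_add_child(tr, "event")
      xes_attr_node(e, "concept:name", ev$name[i])
      xes_attr_node(e, "activity:code", ev$code[i])
      xes_attr_node(e, "lifecycle:transition", ev$lifecycle[i])
      xes_attr_node(e, "time:timestamp", ev$timestamp[i])
      for (col in attr_cols) {
        v <- ev[[col]][i]
        if (!is.na(v)) xes_attr_node(e, col, v)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# parse one typed attribute node into an R value
xes_attr_value <- function(node) {
  v <- xml2::xml_attr(node, "value")
  switch(xml2::xml_name(node),
         date = parse_xes_time(v),
         int = as.integer(v),
         float = as.numeric(v),
         boolean = identical(v, "true"),
         v)
}

#' Read an XES event log
#'
#' Assembles patient traces from an XES document and sorts each trace's
#' events ascending in time. Events lacking `lifecycle:transition` default to
#' `"complete"`. Events without an `activity:code` attribute are matched by
#' display name against `ontology` when one is given; otherwise the name
#' itself is used as the code.
#'
#' @param path XES file path.
#' @param ontology Optional `ontology` for name-to-code matching.
#' @return A `careflow_log`.
#' @export
read_xes <- function(path, ontology = NULL) {
  doc <- xml2::read_xml(path)
  traces <- xml2::xml_find_all(doc, "./trace")
  events_list <- list()
  patients_list <- list()
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    kids <- xml2::xml_children(tr)
    is_event <- xml2::xml_name(kids) == "event"
    tr_attrs <- kids[!is_event]
    keys <- xml2::xml_attr(tr_attrs, "key")
    vals <- lapply(tr_attrs, xes_attr_value)
    names(vals) <- keys
    cid <- vals[["concept:name"]]
    if (is.null(cid)) abort(sprintf("trace %d has no concept:name", ti))
    vals[["concept:name"]] <- NULL
    patients_list[[ti]] <- as_tibble(c(list(case_id = as.character(cid)), vals))
    evs <- kids[is_event]
    if (length(evs) == 0L) next
    rows <- lapply(seq_along(evs), function(ei) {
      e <- evs[[ei]]
      an <- xml2::xml_children(e)
      akeys <- xml2::xml_attr(an, "key")
      avals <- lapply(an, xes_attr_value)
      names(avals) <- akeys
      nm <- avals[["concept:name"]]
      ts <- avals[["time:timestamp"]]
      if (is.null(ts) || is.na(ts)) {
        abort(sprintf("event %d of trace '%s' has no valid time:timestamp", ei, cid))
      }
      code <- avals[["activity:code"]]
      if (is.null(code)) {
        code <- if (!is.null(ontology) && nm %in% ontology$name) {
          ontology$code[match(nm, ontology$name)]
        } else {
          nm
        }
      }
      lc <- avals[["lifecycle:transition"]]
      if (is.null(lc)) lc <- "complete"
      extra <- avals[setdiff(names(avals),
                             c("concept:name", "activity:code",
                               "lifecycle:transition", "time:timestamp"))]
      as_tibble(c(list(case_id = as.character(cid), code = code,
                       name = if (is.null(nm)) code else nm,
                       lifecycle = lc, timestamp = ts), extra))
    })
    events_list[[ti]] <- bind_rows(rows)
  }
  events <- bind_rows(events_list)
  patients <- bind_rows(patients_list)
  if (nrow(patients) == 0L) patients <- tibble(case_id = character())
  if (nrow(events) == 0L) {
    events <- tibble(case_id = character(), code = character(), name = character(),
                     lifecycle = character(),
                     timestamp = as.POSIXct(character(), tz = "UTC"))
  }
  event_log(events, patients, metadata = list(source = path))
}
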