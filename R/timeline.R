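# --- timeline enhancement ----------------------------------------------------
#
# The time perspective: each activity is placed at its median minutes from
# the anchor (hospital arrival, time zero). Events before arrival carry
# negative offsets. Node labels follow the "Name(freq_ratio,median)"
# convention, e.g. "ECG(0.40,8.5)".

#' Minutes from the anchor event, per activity occurrence
#'
#' Maps every complete-lifecycle event of each trace to its signed offset in
#' minutes from the trace's anchor event (negative before the anchor).
#' Repeated activities contribute one offset per occurrence.
#'
#' @param log A `careflow_log` in which every trace contains exactly one
#'   complete-lifecycle anchor event.
#' @param anchor Anchor activity code (hospital arrival by default).
#' @return Tibble `case_id, code, name, minutes` in trace order.
#' @export
relative_minutes <- function(log, anchor = anchor_code()) {
  stopifnot(is_careflow_log(log))
  ev <- log$events[log$events$lifecycle == "complete", , drop = FALSE]
  anchors <- ev[ev$code == anchor, c("case_id", "timestamp")]
  n_anchor <- table(factor(anchors$case_id, levels = case_ids(log)))
  bad <- names(n_anchor)[n_anchor != 1L]
  if (length(bad) > 0L) {
    abort(sprintf("anchor '%s' missing or duplicated in case(s): %s",
                  anchor, paste(bad, collapse = ", ")))
  }
  t0 <- anchors$timestamp[match(ev$case_id, anchors$case_id)]
  tibble(case_id = ev$case_id, code = ev$code, name = ev$name,
         minutes = round(as.numeric(difftime(ev$timestamp, t0, units = "mins")), 1))
}

#' Per-activity timing statistics of a cohort
#'
#' For each activity: the number of distinct patients performing it, the
#' frequency ratio (that number over the cohort size), and the minimum,
#' median and maximum minutes from the anchor. By default only each
#' patient's first occurrence of an activity contributes an offset, so
#' repeated lab tests do not skew the medians; `occurrences = "all"` pools
#' every occurrence instead. `freq_mode = "events"` replaces the
#' patient-count numerator of the ratio by the raw event count.
#'
#' @param cohort A `careflow_cohort` (or a `careflow_log`).
#' @param anchor Anchor activity code.
#' @param occurrences `"first"` (default) or `"all"`.
#' @param freq_mode `"patients"` (default) or `"events"`.
#' @param ontology Optional `ontology`; when given, a `category` column is
#'   attached.
#' @return An `activity_time_stats` tibble: `code, name, category,
#'   n_patients, n_events, freq_ratio, min_minutes, median_minutes,
#'   max_minutes`.
#' @export
compute_stats <- function(cohort, anchor = anchor_code(),
                          occurrences = c("first", "all"),
                          freq_mode = c("patients", "events"),
                          ontology = NULL) {
  occurrences <- match.arg(occurrences)
  freq_mode <- match.arg(freq_mode)
  log <- if (is_cohort(cohort)) cohort$log else cohort
  stopifnot(is_careflow_log(log))
  n <- n_traces(log)
  if (n == 0L) abort("cannot compute stats for an empty cohort")
  offs <- relative_minutes(log, anchor)
  if (occurrences == "first") {
    # events are time-ordered, so the first row per (case, activity) is the
    # earliest occurrence
    offs_used <- distinct(offs, .data$case_id, .data$code, .keep_all = TRUE)
  } else {
    offs_used <- offs
  }
  ev_n <- count(offs, .data$code, name = "n_events")
  stats <- offs_used %>%
    group_by(.data$code, .data$name) %>%
    summarise(n_patients = length(unique(.data$case_id)),
              min_minutes = min(.data$minutes),
              median_minutes = median(.data$minutes),
              max_minutes = max(.data$minutes),
              .groups = "drop")
  stats$n_events <- ev_n$n_events[match(stats$code, ev_n$code)]
  stats$freq_ratio <- if (freq_mode == "patients") {
    stats$n_patients / n
  } else {
    stats$n_events / n
  }
  stats$category <- if (!is.null(ontology)) {
    ontology$category[match(stats$code, ontology$code)]
  } else {
    NA_character_
  }
  stats <- arrange(stats[, c("code", "name", "category", "n_patients", "n_events",
                             "freq_ratio", "min_minutes", "median_minutes",
                             "max_minutes")],
                   .data$median_minutes, .data$code)
  class(stats) <- c("activity_time_stats", class(stats))
  stats
}

#' Timeline node label
#'
#' Formats the "Name(freq_ratio,median_minutes)" node annotation, ratio to
#' two decimals and minutes to one, e.g. `"ECG(0.40,8.5)"`.
#'
#' @param name Activity display name(s).
#' @param freq_ratio Frequency ratio(s) in `[0, 1]`.
#' @param median_minutes Median minutes from the anchor.
#' @export
timeline_label <- function(name, freq_ratio, median_minutes) {
  sprintf("%s(%.2f,%.1f)", name, freq_ratio, median_minutes)
}

#' Enhance a dependency graph with the time perspective
#'
#' Attaches per-activity timing statistics to a discovered dependency graph:
#' each node's display time is its median minutes from the anchor (the
#' anchor itself sits at zero), nodes are ordered chronologically for
#' layout, and labels follow the `"Name(ratio,median)"` convention.
#'
#' @param graph A `dependency_graph` from [discover()].
#' @param stats An `activity_time_stats` covering every graph node.
#' @param anchor Anchor activity code.
#' @return A `timed_dependency_graph`: the graph plus `stats`, `anchor`, and
#'   nodes augmented with `display_time` and `label`, sorted by display time.
#' @export
enhance <- function(graph, stats, anchor = anchor_code()) {
  stopifnot(inherits(graph, "dependency_graph"))
  nodes <- graph$nodes
  missing_nodes <- setdiff(nodes$code, stats$code)
  if (length(missing_nodes) > 0L) {
    abort(sprintf("no timing stats for node(s): %s",
                  paste(missing_nodes, collapse = ", ")))
  }
  idx <- match(nodes$code, stats$code)
  nodes$category <- stats$category[idx]
  nodes$display_time <- stats$median_minutes[idx]
  nodes$label <- timeline_label(nodes$name, nodes$freq_ratio, nodes$display_time)
  nodes <- arrange(nodes, .data$display_time, .data$code)
  structure(list(nodes = nodes, edges = graph$edges,
                 thresholds = graph$thresholds, n_traces = graph$n_traces,
                 stats = stats, anchor = anchor),
            class = c("timed_dependency_graph", "dependency_graph"))
}

#' @export
print.timed_dependency_graph <- function(x, ...) {
  cat(sprintf(
    "<timed_dependency_graph> %d nodes, %d edges, anchor '%s' at 0 min, span %g..%g min\n",
    nrow(x$nodes), nrow(x$edges), x$anchor,
    min(x$nodes$display_time), max(x$nodes$display_time)))
  invisible(x)
}

#' Write an activity timing-statistics table as CSV
#'
#' @param stats An `activity_time_stats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
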