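# --- dependency-graph discovery ----------------------------------------------
#
# Directly-follows counting over complete-lifecycle events plus the classic
# heuristics-miner dependency measure:
#   a != b:  (|a>b| - |b>a|) / (|a>b| + |b>a| + 1)   in (-1, 1)
#   a == b:   |a>a| / (|a>a| + 1)                    in [0, 1)
# The measure is isolated here so an alternative definition can be swapped
# in without touching the rest of the pipeline.

#' Count the directly-follows relation of a log
#'
#' Counts, per ordered activity pair (a, b), how often an event of activity
#' a is immediately followed by one of activity b within a trace. Only
#' complete-lifecycle events enter the counting (start events would double
#' count activities whose start equals their completion). Also tallies each
#' activity's event count and the number of distinct patients whose trace
#' contains it.
#'
#' @param log A `careflow_log` with time-ordered traces.
#' @return A `dfg_counts` list: `pairs` (tibble `from, to, n`),
#'   `activity_freq`, `patient_freq`, `names` (code-to-display-name map),
#'   `n_traces`.
#' @export
count_directly_follows <- function(log) {
  stopifnot(is_careflow_log(log))
  ev <- log$events[log$events$lifecycle == "complete",
                   c("case_id", "code", "name")]
  nm <- ev[!duplicated(ev$code), c("code", "name")]
  act_freq <- count(ev, .data$code, name = "n_events")
  pat_freq <- count(distinct(ev, .data$case_id, .data$code), .data$code,
                    name = "n_patients")
  pairs <- ev %>%
    group_by(.data$case_id) %>%
    mutate(to = lead(.data$code)) %>%
    ungroup() %>%
    filter(!is.na(.data$to)) %>%
    count(from = .data$code, .data$to, name = "n")
  structure(list(pairs = pairs, activity_freq = act_freq,
                 patient_freq = pat_freq, names = nm,
                 n_traces = n_traces(log)),
            class = "dfg_counts")
}

df_count <- function(counts, a, b) {
  hit <- counts$pairs$from == a & counts$pairs$to == b
  if (any(hit)) counts$pairs$n[hit][1] else 0L
}

#' Heuristics-miner dependency measure
#'
#' Signed strength of the causal ordering between two activities, computed
#' from directly-follows counts. Antisymmetric for distinct activities:
#' `dependency_measure(a, b, .) == -dependency_measure(b, a, .)`.
#'
#' @param a,b Activity codes.
#' @param counts A `dfg_counts` from [count_directly_follows()].
#' @return A value in (-1, 1) for `a != b`, in `[0, 1)` for self-loops.
#' @export
dependency_measure <- function(a, b, counts) {
  stopifnot(inherits(counts, "dfg_counts"))
  if (identical(a, b)) {
    n <- df_count(counts, a, a)
    n / (n + 1)
  } else {
    ab <- df_count(counts, a, b)
    ba <- df_count(counts, b, a)
    (ab - ba) / (ab + ba + 1)
  }
}

#' Discover a dependency graph from an event log
#'
#' Retains the activities whose patient-frequency ratio (share of traces
#' containing the activity) reaches `freq_ratio_threshold`, then connects
#' retained pairs observed in the directly-follows relation whose dependency
#' measure reaches `dep_threshold`. Raising either threshold never adds
#' nodes or edges; the result is invariant to trace order.
#'
#' @param log A non-empty `careflow_log`.
#' @param dep_threshold Dependency threshold in `[0, 1)`.
#' @param freq_ratio_threshold Patient-frequency-ratio threshold in `[0, 1]`.
#' @return A `dependency_graph`: `nodes` (tibble `code, name, n_events,
#'   n_patients, freq_ratio`), `edges` (tibble `from, to, dependency,
#'   frequency`), `thresholds`, `n_traces`.
#' @export
discover <- function(log, dep_threshold = 0.9, freq_ratio_threshold = 0.05) {
  stopifnot(is_careflow_log(log))
  if (n_traces(log) == 0L || nrow(log$events) == 0L) {
    abort("cannot discover a model from an empty log")
  }
  if (!is.numeric(dep_threshold) || dep_threshold < 0 || dep_threshold >= 1) {
    abort("dep_threshold must lie in [0, 1)")
  }
  if (!is.numeric(freq_ratio_threshold) || freq_ratio_threshold < 0 ||
      freq_ratio_threshold > 1) {
    abort("freq_ratio_threshold must lie in [0, 1]")
  }
  counts <- count_directly_follows(log)
  nodes <- counts$patient_freq
  nodes$freq_ratio <- nodes$n_patients / counts$n_traces
  nodes <- nodes[nodes$freq_ratio >= freq_ratio_threshold, , drop = FALSE]
  nodes$name <- counts$names$name[match(nodes$code, counts$names$code)]
  nodes$n_events <- counts$activity_freq$n_events[
    match(nodes$code, counts$activity_freq$code)]
  nodes <- arrange(nodes[, c("code", "name", "n_events", "n_patients", "freq_ratio")],
                   .data$code)

  edges <- counts$pairs[counts$pairs$from %in% nodes$code &
                          counts$pairs$to %in% nodes$code, , drop = FALSE]
  if (nrow(edges) > 0L) {
    edges$dependency <- vapply(seq_len(nrow(edges)), function(i) {
      dependency_measure(edges$from[i], edges$to[i], counts)
    }, numeric(1))
    edges <- edges[edges$dependency >= dep_threshold, , drop = FALSE]
  } else {
    edges$dependency <- numeric(0)
  }
  edges <- arrange(rename(edges, frequency = "n")[, c("from", "to", "dependency",
                                                      "frequency")],
                   .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(dep_threshold = dep_threshold,
                                   freq_ratio_threshold = freq_ratio_threshold),
                 n_traces = counts$n_traces),
            class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat(sprintf(
    "<dependency_graph> %d nodes, %d edges (dep >= %.2f, freq ratio >= %.2f, %d traces)\n",
    nrow(x$nodes), nrow(x$edges), x$thresholds$dep_threshold,
    x$thresholds$freq_ratio_threshold, x$n_traces))
  invisible(x)
}
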