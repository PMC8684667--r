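# --- DOT / JSON export of timed dependency graphs ----------------------------
#
# Visual conventions: nodes are boxes colored by category (Observation
# green, Drug red, Artificial black, Evaluation orange, Operation blue),
# labelled "Name(freq_ratio,median_minutes)"; a time axis of tick nodes runs
# down the left side and nodes sharing a time bin share a rank, so the
# layout is chronological.

#' Rendering specification
#'
#' @param colors Named character vector mapping all five categories to fill
#'   colors.
#' @param bin_minutes Width of the time bins used for same-rank grouping and
#'   axis ticks.
#' @return A `render_spec` list.
#' @export
render_spec <- function(colors = c(Evaluation = "orange", Observation = "green",
                                   Drug = "red", Operation = "blue",
                                   Artificial = "black"),
                        bin_minutes = 5) {
  needed <- c("Evaluation", "Observation", "Drug", "Operation", "Artificial")
  missing_cat <- setdiff(needed, names(colors))
  if (length(missing_cat) > 0L) {
    abort(sprintf("render spec must map all five categories; missing: %s",
                  paste(missing_cat, collapse = ", ")))
  }
  stopifnot(is.numeric(bin_minutes), bin_minutes > 0)
  structure(list(colors = colors, bin_minutes = bin_minutes),
            class = "render_spec")
}

dot_quote <- function(x) {
  paste0('"', gsub('"', '\\\\"', x), '"')
}

#' Render a timed dependency graph as DOT text
#'
#' Deterministic for a fixed graph: nodes are emitted in display-time order
#' (ties broken by code). Every node must carry a mapped category.
#'
#' @param graph A `timed_dependency_graph` from [enhance()].
#' @param spec A [render_spec()].
#' @return A single DOT string (Graphviz dialect).
#' @export
to_dot <- function(graph, spec = render_spec()) {
  stopifnot(inherits(graph, "timed_dependency_graph"),
            inherits(spec, "render_spec"))
  nodes <- graph$nodes
  unmapped <- is.na(nodes$category) | !nodes$category %in% names(spec$colors)
  if (any(unmapped)) {
    abort(sprintf("unmapped category for node(s): %s",
                  paste(nodes$code[unmapped], collapse = ", ")))
  }
  node_id <- setNames(sprintf("n%d", seq_len(nrow(nodes))), nodes$code)
  fill <- spec$colors[nodes$category]
  font <- ifelse(fill %in% c("black", "blue", "red"), "white", "black")
  lines <- c("digraph timed_dependency_graph {",
             "  rankdir=TB;",
             "  node [shape=box, style=filled];")
  # time axis: an invisible chain of tick nodes, one per occupied bin
  bw <- spec$bin_minutes
  bins <- sort(unique(floor(nodes$display_time / bw) * bw))
  tick_id <- setNames(sprintf("t%d", seq_along(bins)), as.character(bins))
  for (b in as.character(bins)) {
    lines <- c(lines, sprintf(
      "  %s [shape=plaintext, style=solid, label=%s];",
      tick_id[[b]], dot_quote(sprintf("%g min", as.numeric(b)))))
  }
  if (length(bins) > 1L) {
    chain <- paste(tick_id, collapse = " -> ")
    lines <- c(lines, sprintf("  %s [style=invis];", chain))
  }
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines, sprintf(
      "  %s [label=%s, fillcolor=%s, fontcolor=%s];",
      node_id[[nodes$code[i]]], dot_quote(nodes$label[i]),
      dot_quote(unname(fill[i])), dot_quote(unname(font[i]))))
  }
  for (b in as.character(bins)) {
    members <- node_id[nodes$code[floor(nodes$display_time / bw) * bw ==
                                    as.numeric(b)]]
    lines <- c(lines, sprintf("  { rank=same; %s; %s; }",
                              tick_id[[b]], paste(members, collapse = "; ")))
  }
  edges <- graph$edges
  if (nrow(edges) > 0L) {
    edges <- arrange(edges, .data$from, .data$to)
    for (i in seq_len(nrow(edges))) {
      lines <- c(lines, sprintf(
        "  %s -> %s [label=%s];",
        node_id[[edges$from[i]]], node_id[[edges$to[i]]],
        dot_quote(sprintf("%.2f", edges$dependency[i]))))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Write a timed dependency graph as DOT
#'
#' @param graph A `timed_dependency_graph`.
#' @param path Output path.
#' @param spec A [render_spec()].
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path, spec = render_spec()) {
  writeLines(to_dot(graph, spec), path)
  invisible(path)
}

#' Write a timed dependency graph as JSON
#'
#' Nodes with their annotations (frequency ratio, display time, label,
#' category) and edges with dependency value and frequency.
#'
#' @param graph A `timed_dependency_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "timed_dependency_graph"))
  payload <- list(anchor = graph$anchor,
                  n_traces = graph$n_traces,
                  thresholds = graph$thresholds,
                  nodes = graph$nodes,
                  edges = graph$edges)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a timed dependency graph from JSON
#'
#' @param path JSON path written by [write_graph_json()].
#' @return A `timed_dependency_graph`.
#' @export
read_graph_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as_tibble(payload$nodes)
  edges <- as_tibble(payload$edges)
  if (nrow(edges) == 0L) {
    edges <- tibble(from = character(), to = character(),
                    dependency = numeric(), frequency = integer())
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = payload$thresholds, n_traces = payload$n_traces,
                 stats = NULL, anchor = payload$anchor),
            class = c("timed_dependency_graph", "dependency_graph"))
}
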