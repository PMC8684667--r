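# Test utilities: small random logs, an independent brute-force
# directly-follows oracle, and a minimal DOT well-formedness checker.

t0 <- function() as.POSIXct("2020-06-01 08:00:00", tz = "UTC")

# random log over arbitrary activity codes; caller controls the RNG state
random_log <- function(n_traces = 5, activities = LETTERS[1:5], max_len = 8) {
  events <- list()
  for (i in seq_len(n_traces)) {
    len <- sample(1:max_len, 1)
    codes <- sample(activities, len, replace = TRUE)
    events[[i]] <- tibble::tibble(
      case_id = sprintf("T%03d", i),
      code = codes, name = codes, lifecycle = "complete",
      timestamp = t0() + 86400 * i + 60 * cumsum(sample(1:30, len, replace = TRUE)))
  }
  event_log(dplyr::bind_rows(events))
}

# brute-force pairwise scan, written independently of the package counter:
# walks each trace's complete events in time order and increments a matrix
bf_df_matrix <- function(log, activities) {
  m <- matrix(0L, length(activities), length(activities),
              dimnames = list(activities, activities))
  ev <- log$events[log$events$lifecycle == "complete", ]
  for (cid in unique(ev$case_id)) {
    tr <- ev[ev$case_id == cid, ]
    tr <- tr[order(tr$timestamp, match(tr$lifecycle, c("start", "complete")),
                   tr$code), ]
    if (nrow(tr) < 2) next
    for (k in 1:(nrow(tr) - 1)) {
      m[tr$code[k], tr$code[k + 1]] <- m[tr$code[k], tr$code[k + 1]] + 1L
    }
  }
  m
}

# pair count straight off the counts table
df_count_pair <- function(counts, a, b) {
  hit <- counts$pairs$from == a & counts$pairs$to == b
  if (any(hit)) counts$pairs$n[hit][1] else 0L
}

bf_dependency <- function(a, b, m) {
  if (a == b) m[a, a] / (m[a, a] + 1) else
    (m[a, b] - m[b, a]) / (m[a, b] + m[b, a] + 1)
}

# minimal structural check of a DOT digraph: balanced braces/quotes and
# every statement a recognized node, edge, chain or subgraph line
check_dot <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  n_open <- sum(lengths(regmatches(lines, gregexpr("\\{", lines))))
  n_close <- sum(lengths(regmatches(lines, gregexpr("\\}", lines))))
  if (n_open != n_close) return(FALSE)
  if (!grepl("^digraph\\s+\\w+\\s*\\{$", lines[1])) return(FALSE)
  if (tail(lines, 1) != "}") return(FALSE)
  body <- lines[-c(1, length(lines))]
  id <- "[A-Za-z_][A-Za-z0-9_]*"
  attrs <- "\\[[^\\]]*\\]"
  ok <- grepl(sprintf("^\\s*%s\\s*(%s)?\\s*;$", id, attrs), body,
              perl = TRUE) |                                                # node
    grepl(sprintf("^\\s*%s(\\s*->\\s*%s)+\\s*(%s)?\\s*;$", id, id, attrs),  # edge
          body, perl = TRUE) |
    grepl(sprintf("^\\s*\\{\\s*rank=same;(\\s*%s;)+\\s*\\}$", id), body,
          perl = TRUE) |                                                    # rank
    grepl("^\\s*(node|edge|graph)\\s*\\[[^\\]]*\\]\\s*;$", body,
          perl = TRUE) |                                                    # defaults
    grepl("^\\s*rankdir=\\w+;$", body)
  if (!all(ok)) return(FALSE)
  # quotes must pair up on every line
  all(lengths(regmatches(body, gregexpr('"', body))) %% 2 == 0)
}

# tiny ontology-coded log used across modules
tiny_clinical_log <- function() {
  arr <- t0()
  events <- tibble::tibble(
    case_id = "P1",
    code = c("C.O.1.1", "C.O.2.1", "C.O.2.1", "C.D.3.1", "C.D.3.1"),
    name = c("ECG", "Head CT", "Head CT", "rt-PA", "rt-PA"),
    lifecycle = c("complete", "start", "complete", "start", "complete"),
    timestamp = arr + 60 * c(9, 78, 84, 117, 177),
    stage = c("emergency", "emergency", "emergency",
              "hospitalization", "hospitalization"),
    dose_mg = c(NA, NA, NA, 63, NA))
  patients <- tibble::tibble(
    case_id = "P1", onset_time = arr - 60 * 80, arrival_time = arr,
    neurology_arrival_time = arr + 60 * 110)
  event_log(events, patients)
}
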