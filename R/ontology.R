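#' Category letters of the activity coding scheme
#'
#' The second segment of an activity code names its top-level clinical
#' category. The default letter set maps E to Evaluation, O to Observation,
#' D to Drug, P to Operation and A to Artificial (milestone events such as
#' symptom onset or hospital arrival that are derived from patient attributes
#' rather than clinical orders). An alternative letter table can be supplied
#' to every function that takes `category_letters`.
#'
#' @return Named character vector mapping letter to category name.
#' @export
default_category_letters <- function() {
  c(E = "Evaluation", O = "Observation", D = "Drug",
    P = "Operation", A = "Artificial")
}

#' Parse a hierarchical activity code
#'
#' Activity codes are dot-separated paths in the activity classification
#' tree, e.g. `"C.D.1.1.1.1"`: `C` marks a clinical activity, the second
#' segment the category (e.g. `D` for drug), deeper segments successive
#' subclasses. A trailing dot (as in `"C.D.1.1.1."`) is tolerated on input
#' and never emitted. Each segment must be a single letter or a positive
#' integer; codes are identifiers, so numeric segments compare as text.
#'
#' @param text Single code string.
#' @param category_letters Named letter-to-category table,
#'   see [default_category_letters()].
#' @return An `activity_code` object: a list with `levels` (character vector
#'   of path segments) and `code` (canonical dotted form).
#' @examples
#' parse_code("C.D.1.1.1.1")$levels
#' parse_code("C.D.1.1.1.")$code  # trailing dot dropped
#' @export
parse_code <- function(text, category_letters = default_category_letters()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort("activity code must be a single non-empty string")
  }
  raw <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(raw) == 0L) {
    abort(sprintf("malformed activity code '%s': no segments", text))
  }
  # a trailing dot yields one trailing empty segment; drop it
  if (raw[length(raw)] == "") raw <- raw[-length(raw)]
  if (length(raw) == 0L) {
    abort(sprintf("malformed activity code '%s': no segments", text))
  }
  bad <- which(!grepl("^([A-Za-z]|[1-9][0-9]*)$", raw))
  if (length(bad) > 0L) {
    abort(sprintf("malformed activity code '%s': invalid segment '%s' at position %d",
                  text, raw[bad[1]], bad[1]))
  }
  if (raw[1] != "C") {
    abort(sprintf("malformed activity code '%s': first segment must be 'C', got '%s'",
                  text, raw[1]))
  }
  if (length(raw) >= 2L && !raw[2] %in% names(category_letters)) {
    abort(sprintf("malformed activity code '%s': unknown category letter '%s'",
                  text, raw[2]))
  }
  structure(list(levels = raw, code = paste(raw, collapse = ".")),
            class = "activity_code")
}

#' @export
format.activity_code <- function(x, ...) x$code

#' @export
print.activity_code <- function(x, ...) {
  cat("<activity_code> ", x$code, " (depth ", length(x$levels), ")\n", sep = "")
  invisible(x)
}

#' @export
as.character.activity_code <- function(x, ...) x$code

# vectorized segment count of dotted codes (no validation)
code_depth <- function(codes) {
  lengths(strsplit(codes, ".", fixed = TRUE))
}

#' Ancestor of a code at a given depth
#'
#' Returns the prefix of the code path with at most `depth` segments. Codes
#' already at or above the requested depth are returned unchanged, so the
#' operation is safe to apply uniformly across a log. Vectorized over codes.
#'
#' @param code Character vector of dotted codes (or a single `activity_code`).
#' @param depth Positive integer, target number of segments.
#' @return Character vector of truncated codes.
#' @examples
#' ancestor_at_depth("C.D.1.1.1.1", 2)  # "C.D"
#' @export
ancestor_at_depth <- function(code, depth) {
  if (inherits(code, "activity_code")) code <- code$code
  stopifnot(is.numeric(depth), length(depth) == 1L, depth >= 1)
  depth <- as.integer(depth)
  parts <- strsplit(code, ".", fixed = TRUE)
  vapply(parts, function(p) paste(p[seq_len(min(depth, length(p)))], collapse = "."),
         character(1))
}

# parent code (one segment shorter); "" for depth-1 codes
code_parent <- function(codes) {
  parts <- strsplit(codes, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) <= 1L) "" else paste(p[-length(p)], collapse = ".")
  }, character(1))
}

#' Load an activity ontology
#'
#' Reads a hierarchical activity classification from a delimited text file
#' (columns `code,name,category`) or a data frame. Every non-root record's
#' parent code must also be present; the category of nodes deeper than two
#' segments is inherited from their depth-2 ancestor unless stated
#' explicitly in the `category` column.
#'
#' @param source File path or data frame with columns `code`, `name` and
#'   optionally `category`.
#' @param category_letters Letter-to-category table.
#' @return An `ontology` tibble with columns `code`, `name`, `category`,
#'   `depth`, `parent`, sorted by code.
#' @export
load_ontology <- function(source, category_letters = default_category_letters()) {
  df <- if (is.character(source)) {
    read.csv(source, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  } else {
    as.data.frame(source, stringsAsFactors = FALSE)
  }
  if (!all(c("code", "name") %in% names(df))) {
    abort("ontology source must have columns 'code' and 'name'")
  }
  if (!"category" %in% names(df)) df$category <- NA_character_
  codes <- vapply(df$code, function(x) parse_code(x, category_letters)$code,
                  character(1), USE.NAMES = FALSE)
  dup <- codes[duplicated(codes)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate ontology code(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  depth <- code_depth(codes)
  parent <- code_parent(codes)
  orphan <- depth > 1L & !parent %in% codes
  if (any(orphan)) {
    abort(sprintf("orphan ontology record(s), parent missing: %s",
                  paste(codes[orphan], collapse = ", ")))
  }
  bad_cat <- !is.na(df$category) & !df$category %in% category_letters
  if (any(bad_cat)) {
    abort(sprintf("unknown category name(s): %s",
                  paste(unique(df$category[bad_cat]), collapse = ", ")))
  }
  # category from the depth-2 ancestor's letter unless stated explicitly
  letter <- vapply(strsplit(codes, ".", fixed = TRUE),
                   function(p) if (length(p) >= 2L) p[2] else NA_character_,
                   character(1))
  inferred <- unname(category_letters[letter])
  category <- ifelse(is.na(df$category), inferred, df$category)
  out <- tibble(code = codes, name = as.character(df$name),
                category = category, depth = depth, parent = parent)
  out <- arrange(out, .data$code)
  class(out) <- c("ontology", class(out))
  out
}

#' The packaged stroke activity ontology
#'
#' A compact clinical-activity classification for the acute ischemic stroke
#' pathway: the five display categories (Evaluation, Observation, Drug,
#' Operation, Artificial), a penicillin chain down to `C.D.1.1.1.1`
#' (Benzylpenicillin), antihypertensives, thrombolytics (rt-PA, urokinase),
#' ECG/CT/MRI and laboratory tests, nursing operations, and the three
#' artificial milestone events under `C.A`.
#'
#' @return An `ontology` tibble.
#' @export
stroke_ontology <- function() {
  path <- system.file("extdata", "stroke_ontology.csv", package = "careflow",
                      mustWork = TRUE)
  load_ontology(path)
}

is_ontology <- function(x) inherits(x, "ontology")

#' Look up ontology nodes by code
#'
#' @param ontology An `ontology` tibble.
#' @param code Character vector of canonical codes.
#' @return Tibble of matching rows in the order of `code`; unknown codes
#'   yield rows of `NA`.
#' @export
ontology_lookup <- function(ontology, code) {
  stopifnot(is_ontology(ontology))
  idx <- match(code, ontology$code)
  as_tibble(ontology)[idx, , drop = FALSE]
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d nodes, max depth %d, %d leaves\n",
              nrow(x), max(x$depth),
              sum(!x$code %in% x$parent)))
  NextMethod()
}

#' Abstract an event log to a shallower ontology level
#'
#' Replaces every event's activity by its ancestor at the requested depth and
#' relabels it with the ancestor's display name, shrinking the number of
#' distinct event types (e.g. Nitrendipine and Nifedipine both abstract to
#' antihypertensive drugs). Events in the Artificial category are milestones,
#' not clinical orders, and pass through unchanged. Timestamps, lifecycles,
#' event counts and ordering are untouched; the operation is idempotent at a
#' fixed depth.
#'
#' @param log A `careflow_log`.
#' @param depth Positive integer aggregation depth (number of code segments).
#' @param ontology An `ontology` resolving every non-artificial event code.
#' @return The abstracted `careflow_log`.
#' @export
aggregate_log <- function(log, depth, ontology = stroke_ontology()) {
  stopifnot(is_careflow_log(log), is_ontology(ontology))
  ev <- log$events
  if (nrow(ev) == 0L) return(log)
  cat_of <- ontology$category[match(ev$code, ontology$code)]
  artificial <- !is.na(cat_of) & cat_of == "Artificial"
  unknown <- unique(ev$code[!artificial & !ev$code %in% ontology$code])
  if (length(unknown) > 0L) {
    abort(sprintf("event code(s) not in ontology: %s",
                  paste(unknown, collapse = ", ")))
  }
  new_code <- ev$code
  new_code[!artificial] <- ancestor_at_depth(ev$code[!artificial], depth)
  new_name <- ev$name
  new_name[!artificial] <- ontology$name[match(new_code[!artificial], ontology$code)]
  ev$code <- new_code
  ev$name <- new_name
  log$events <- ev
  log
}
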