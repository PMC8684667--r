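# --- cohort splitting and observation-window truncation ----------------------

new_cohort <- function(label, log, window_minutes = NA_real_) {
  structure(list(label = label, log = log, window_minutes = window_minutes),
            class = "careflow_cohort")
}

#' @export
is_cohort <- function(x) inherits(x, "careflow_cohort")

#' @export
print.careflow_cohort <- function(x, ...) {
  cat(sprintf("<careflow_cohort> '%s', %d patients%s\n", x$label,
              n_traces(x$log),
              if (is.finite(x$window_minutes))
                sprintf(", window %g min", x$window_minutes) else ""))
  invisible(x)
}

#' Split a cleaned log into thrombolysis and non-thrombolysis cohorts
#'
#' Partition by whether the patient received intravenous thrombolysis
#' therapy, i.e. whether a thrombolytic-drug order yields a needle time.
#' Every trace lands in exactly one cohort; the split is deterministic and
#' independent of trace order.
#'
#' @param log A cleaned `careflow_log`.
#' @param config A [careflow_config()].
#' @return List with `thrombolysis` and `non_thrombolysis` cohorts.
#' @export
split_cohorts <- function(log, config = careflow_config()) {
  stopifnot(is_careflow_log(log))
  config <- as_config(config)
  ndl <- derive_needle_time(log, config)
  with_needle <- ndl$case_id[!is.na(ndl$needle_time)]
  without <- setdiff(case_ids(log), with_needle)
  list(
    thrombolysis = new_cohort("thrombolysis", filter_cases(log, with_needle)),
    non_thrombolysis = new_cohort("non_thrombolysis", filter_cases(log, without))
  )
}

#' Truncate a cohort to an observation window after arrival
#'
#' Without a thrombolytic drug there is no natural last event, so the
#' non-thrombolysis process is bounded to the activities within a fixed
#' window after hospital arrival (default 3 h: the thrombolysis cohort's 2-h
#' median door-to-needle time plus the 1-h infusion). Events at exactly
#' arrival + window are kept ("within" is inclusive); pre-arrival events
#' (onset) and artificial milestones are always retained. Idempotent at a
#' fixed window; `minutes = Inf` is the identity.
#'
#' @param cohort A `careflow_cohort` whose patients all have `arrival_time`.
#' @param minutes Window length in minutes.
#' @return The truncated cohort, with `window_minutes` recorded.
#' @export
truncate_to_window <- function(cohort, minutes = 180) {
  stopifnot(is_cohort(cohort), is.numeric(minutes), minutes > 0)
  log <- cohort$log
  pats <- log$patients
  if (!"arrival_time" %in% names(pats) || anyNA(pats$arrival_time)) {
    bad <- if ("arrival_time" %in% names(pats)) {
      pats$case_id[is.na(pats$arrival_time)]
    } else {
      pats$case_id
    }
    abort(sprintf("missing arrival_time for case(s): %s", paste(bad, collapse = ", ")))
  }
  ev <- log$events
  arr <- pats$arrival_time[match(ev$case_id, pats$case_id)]
  offset <- as.numeric(difftime(ev$timestamp, arr, units = "mins"))
  keep <- offset <= minutes | is_artificial_code(ev$code)
  log$events <- ev[keep, , drop = FALSE]
  cohort$log <- log
  cohort$window_minutes <- minutes
  cohort
}
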