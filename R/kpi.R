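# --- acute-stroke performance indicators -------------------------------------
#
# Door-to-needle (DNT), imaging-to-needle (INT), onset-to-needle, the share
# of thrombolysed patients treated within 60 min of arrival, and the share
# of 2-h arrivals treated within 3 h of onset. "Within X min" is inclusive
# (<= X), consistent with guideline phrasing. Medians over even counts
# average the middle pair.

#' Door-to-needle time per patient
#'
#' Minutes from hospital arrival to the start of thrombolytic therapy.
#' Patients without a needle time get `NA` (absence, not an error).
#'
#' @param log A `careflow_log`.
#' @param config A [careflow_config()].
#' @return Tibble `case_id, dnt_minutes`.
#' @export
door_to_needle <- function(log, config = careflow_config()) {
  stopifnot(is_careflow_log(log))
  config <- as_config(config)
  ndl <- derive_needle_time(log, config)
  arr <- log$patients$arrival_time[match(ndl$case_id, log$patients$case_id)]
  tibble(case_id = ndl$case_id,
         dnt_minutes = as.numeric(difftime(ndl$needle_time, arr, units = "mins")))
}

#' Imaging-to-needle time per patient
#'
#' Minutes from the completion of the qualifying brain-imaging examination
#' to the start of thrombolytic therapy. By default the last qualifying
#' imaging completion at or before the needle time is used
#' (`mode = "last_before_needle"`); `mode = "first"` takes the patient's
#' first imaging completion instead. `NA` when the patient has no needle
#' time or no qualifying imaging before it.
#'
#' @param log A `careflow_log`.
#' @param config A [careflow_config()] supplying `imaging_codes`.
#' @param mode Imaging-selection mode.
#' @return Tibble `case_id, int_minutes, imaging_completion`.
#' @export
imaging_to_needle <- function(log, config = careflow_config(),
                              mode = c("last_before_needle", "first")) {
  stopifnot(is_careflow_log(log))
  mode <- match.arg(mode)
  config <- as_config(config)
  ndl <- derive_needle_time(log, config)
  ev <- log$events
  img <- ev[ev$lifecycle == "complete" & code_in_set(ev$code, config$imaging_codes),
            c("case_id", "timestamp")]
  needle_of <- ndl$needle_time[match(img$case_id, ndl$case_id)]
  img <- img[!is.na(needle_of) & img$timestamp <= needle_of, , drop = FALSE]
  pick <- if (nrow(img) == 0L) {
    tibble(case_id = character(), imaging_completion = ev$timestamp[0])
  } else {
    summarise(group_by(img, .data$case_id),
              imaging_completion = if (mode == "last_before_needle") {
                max(.data$timestamp)
              } else {
                min(.data$timestamp)
              },
              .groups = "drop")
  }
  out <- tibble(case_id = ndl$case_id)
  out$imaging_completion <- pick$imaging_completion[match(out$case_id, pick$case_id)]
  needle <- ndl$needle_time[match(out$case_id, ndl$case_id)]
  out$int_minutes <- as.numeric(difftime(needle, out$imaging_completion,
                                         units = "mins"))
  out[, c("case_id", "int_minutes", "imaging_completion")]
}

#' Proportion of values within a bound
#'
#' `100 * |{v <= bound}| / |values|`, ignoring `NA`s; `NA` for an empty
#' list. Monotone non-decreasing in the bound.
#'
#' @param values Numeric vector of minutes.
#' @param bound Inclusive upper bound in minutes.
#' @return Percentage in `[0, 100]`, or `NA` if no values.
#' @export
proportion_within <- function(values, bound) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  100 * sum(values <= bound) / length(values)
}

#' Thrombolysis rate of early arrivals
#'
#' Among patients who arrived within 2 h of symptom onset, the percentage
#' treated (needle time) within 3 h of onset. Patients without a needle time
#' stay in the denominator: this is a treatment rate, not a timing summary.
#'
#' @param log A `careflow_log` with onset and arrival attributes.
#' @param config A [careflow_config()].
#' @return Percentage, or `NA` when no patient arrived within 2 h.
#' @export
arrive2h_treated3h <- function(log, config = careflow_config()) {
  stopifnot(is_careflow_log(log))
  config <- as_config(config)
  pats <- log$patients
  if (!all(c("onset_time", "arrival_time") %in% names(pats))) return(NA_real_)
  ndl <- derive_needle_time(log, config)
  needle <- ndl$needle_time[match(pats$case_id, ndl$case_id)]
  o2a <- as.numeric(difftime(pats$arrival_time, pats$onset_time, units = "mins"))
  o2n <- as.numeric(difftime(needle, pats$onset_time, units = "mins"))
  denom <- !is.na(o2a) & o2a <= 120
  if (!any(denom)) return(NA_real_)
  numer <- denom & !is.na(o2n) & o2n <= 180
  100 * sum(numer) / sum(denom)
}

#' KPI report for a cohort
#'
#' Assembles the per-patient timing lists, their medians and the proportion
#' indicators, and attaches the configured published reference values.
#' Cohorts without thrombolysed patients yield a report whose needle-based
#' KPIs are absent.
#'
#' @param cohort A `careflow_cohort` (or `careflow_log`).
#' @param config A [careflow_config()].
#' @return A `kpi_report` list.
#' @export
kpi_report <- function(cohort, config = careflow_config()) {
  config <- as_config(config)
  log <- if (is_cohort(cohort)) cohort$log else cohort
  label <- if (is_cohort(cohort)) cohort$label else "all"
  stopifnot(is_careflow_log(log))
  dnt <- door_to_needle(log, config)
  int <- imaging_to_needle(log, config)
  pats <- log$patients
  onset <- if ("onset_time" %in% names(pats)) pats$onset_time else
    as.POSIXct(rep(NA, nrow(pats)), tz = "UTC")
  needle <- derive_needle_time(log, config)$needle_time
  otn <- as.numeric(difftime(needle, onset, units = "mins"))
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  structure(list(
    label = label,
    n = n_traces(log),
    n_thrombolysed = sum(!is.na(dnt$dnt_minutes)),
    dnt_minutes = dnt,
    dnt_median = med(dnt$dnt_minutes),
    int_minutes = int[, c("case_id", "int_minutes")],
    int_median = med(int$int_minutes),
    onset_to_needle_minutes = tibble(case_id = pats$case_id,
                                     onset_to_needle_minutes = otn),
    onset_to_needle_median = med(otn),
    pct_dnt_within_60 = proportion_within(dnt$dnt_minutes, 60),
    pct_arrive2h_treated3h = arrive2h_treated3h(log, config),
    references = config$kpi_references
  ), class = "kpi_report")
}

#' @export
print.kpi_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f", v)
  cat(sprintf("<kpi_report> cohort '%s' (n = %d, thrombolysed = %d)\n",
              x$label, x$n, x$n_thrombolysed))
  cat(sprintf("  DNT median:             %s min\n", fmt(x$dnt_median)))
  cat(sprintf("  INT median:             %s min\n", fmt(x$int_median)))
  cat(sprintf("  onset-to-needle median: %s min\n", fmt(x$onset_to_needle_median)))
  cat(sprintf("  %% DNT within 60 min:    %s\n", fmt(x$pct_dnt_within_60)))
  cat(sprintf("  %% arrive2h treated3h:   %s\n", fmt(x$pct_arrive2h_treated3h)))
  invisible(x)
}

# flat summary used by the JSON/CSV exports
kpi_summary_row <- function(report) {
  tibble(cohort = report$label, n = report$n,
         n_thrombolysed = report$n_thrombolysed,
         dnt_median_minutes = report$dnt_median,
         int_median_minutes = report$int_median,
         onset_to_needle_median_minutes = report$onset_to_needle_median,
         pct_dnt_within_60 = report$pct_dnt_within_60,
         pct_arrive2h_treated3h = report$pct_arrive2h_treated3h)
}

#' Write KPI reports as JSON or CSV
#'
#' @param reports A `kpi_report` or list of them.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_kpi_report <- function(reports, path) {
  if (inherits(reports, "kpi_report")) reports <- list(reports)
  summ <- bind_rows(lapply(reports, kpi_summary_row))
  if (grepl("\\.json$", path)) {
    payload <- list(cohorts = summ, references = reports[[1]]$references)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    write.csv(as.data.frame(summ), path, row.names = FALSE)
  }
  invisible(path)
}
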