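# --- rule engine: validation filters and timestamp derivations ---------------
#
# Nine preprocessing rules for acute-stroke traces. Rules 1-4 and 7-9 are
# pass/fail filters; rules 5 and 6 derive timestamps (thrombolysis start,
# neurology arrival) and carry no verdict. "Earlier"/"later" are strict
# inequalities throughout: with minute-precision data, ties are frequent and
# count as violations.

rt_pa_code <- function() "C.D.3.1"

validation_rule_ids <- function() c(1L, 2L, 3L, 4L, 7L, 8L, 9L)

#' Derive the start time of thrombolytic therapy (rule 5)
#'
#' The needle time is the start of the earliest thrombolytic-drug order
#' (rt-PA or urokinase by default); when a patient has more than one
#' thrombolytic order the earliest determines the therapy start.
#'
#' @param log A `careflow_log`.
#' @param config A [careflow_config()].
#' @return Tibble `case_id, needle_time` covering every patient; `NA` when no
#'   thrombolytic order exists.
#' @export
derive_needle_time <- function(log, config = careflow_config()) {
  stopifnot(is_careflow_log(log))
  config <- as_config(config)
  ev <- log$events
  hit <- ev$lifecycle == "start" & code_in_set(ev$code, config$thrombolytic_codes)
  needles <- ev[hit, c("case_id", "timestamp")]
  needles <- if (nrow(needles) == 0L) {
    tibble(case_id = character(), needle_time = ev$timestamp[0])
  } else {
    summarise(group_by(needles, .data$case_id),
              needle_time = min(.data$timestamp), .groups = "drop")
  }
  out <- tibble(case_id = log$patients$case_id)
  out$needle_time <- needles$needle_time[match(out$case_id, needles$case_id)]
  out
}

#' Derive the neurology-department arrival time (rule 6)
#'
#' An explicitly recorded `neurology_arrival_time` patient attribute takes
#' precedence. Otherwise, when enabled, the arrival at the neurology
#' department is determined by the first order issued after admission, i.e.
#' the earliest start-lifecycle order flagged with `stage ==
#' "hospitalization"`.
#'
#' @param log A `careflow_log`.
#' @param config A [careflow_config()].
#' @return Tibble `case_id, neurology_arrival_time, derived` (`derived` is
#'   `TRUE` where rule 6 supplied the value).
#' @export
derive_neurology_arrival <- function(log, config = careflow_config()) {
  stopifnot(is_careflow_log(log))
  config <- as_config(config)
  out <- tibble(case_id = log$patients$case_id)
  explicit <- if ("neurology_arrival_time" %in% names(log$patients)) {
    log$patients$neurology_arrival_time
  } else {
    as.POSIXct(rep(NA, nrow(out)), tz = "UTC")
  }
  derived_time <- as.POSIXct(rep(NA, nrow(out)), tz = "UTC")
  if (config$derive_neurology && "stage" %in% names(log$events)) {
    ev <- log$events
    hit <- ev$lifecycle == "start" & !is_artificial_code(ev$code) &
      !is.na(ev$stage) & ev$stage == "hospitalization"
    if (any(hit)) {
      first_ord <- summarise(group_by(ev[hit, c("case_id", "timestamp")],
                                      .data$case_id),
                             t = min(.data$timestamp), .groups = "drop")
      derived_time <- first_ord$t[match(out$case_id, first_ord$case_id)]
    }
  }
  out$neurology_arrival_time <- as.POSIXct(
    ifelse(!is.na(explicit), explicit, derived_time),
    tz = "UTC", origin = "1970-01-01")
  out$derived <- is.na(explicit) & !is.na(derived_time)
  out
}

# per-case facts shared by the rule verdicts and the KPI module
case_facts <- function(log, config) {
  pats <- log$patients
  ev <- log$events
  out <- tibble(case_id = pats$case_id)
  grab <- function(col) {
    if (col %in% names(pats)) pats[[col]] else as.POSIXct(rep(NA, nrow(out)), tz = "UTC")
  }
  out$onset <- grab("onset_time")
  out$arrival <- grab("arrival_time")
  neu <- derive_neurology_arrival(log, config)
  out$neurology <- neu$neurology_arrival_time[match(out$case_id, neu$case_id)]
  out$neurology_derived <- neu$derived[match(out$case_id, neu$case_id)]
  ndl <- derive_needle_time(log, config)
  out$needle <- ndl$needle_time[match(out$case_id, ndl$case_id)]

  is_order <- ev$lifecycle == "start" & !is_artificial_code(ev$code)
  ords <- ev[is_order, c("case_id", "timestamp")]
  ord_sum <- if (nrow(ords) == 0L) {
    tibble(case_id = character(), n_orders = integer(),
           first_order = ev$timestamp[0])
  } else {
    summarise(group_by(ords, .data$case_id),
              n_orders = n(), first_order = min(.data$timestamp),
              .groups = "drop")
  }
  idx <- match(out$case_id, ord_sum$case_id)
  out$n_orders <- ifelse(is.na(idx), 0L, ord_sum$n_orders[idx])
  out$first_order <- ord_sum$first_order[idx]

  # earliest order not strictly after arrival, per case
  arr_of <- out$arrival[match(ords$case_id, out$case_id)]
  early <- ords[!is.na(arr_of) & ords$timestamp <= arr_of, , drop = FALSE]
  early_sum <- summarise(group_by(early, .data$case_id),
                         n_early = n(), .groups = "drop")
  eidx <- match(out$case_id, early_sum$case_id)
  out$n_early_orders <- ifelse(is.na(eidx), 0L, early_sum$n_early[eidx])

  rtpa <- ev$lifecycle == "start" & code_in_set(ev$code, rt_pa_code())
  if ("dose_mg" %in% names(ev)) {
    doses <- ev[rtpa & !is.na(ev$dose_mg), c("case_id", "dose_mg")]
  } else {
    doses <- tibble(case_id = character(), dose_mg = numeric())
  }
  dose_sum <- if (nrow(doses) == 0L) {
    tibble(case_id = character(), n_doses = integer(), dose_ok = logical(),
           dose_bad = character())
  } else {
    summarise(group_by(doses, .data$case_id),
              n_doses = n(),
              dose_ok = all(.data$dose_mg >= config$dose_range[1] &
                              .data$dose_mg <= config$dose_range[2]),
              dose_bad = paste(
                .data$dose_mg[.data$dose_mg < config$dose_range[1] |
                                .data$dose_mg > config$dose_range[2]],
                collapse = ","),
              .groups = "drop")
  }
  didx <- match(out$case_id, dose_sum$case_id)
  out$n_doses <- ifelse(is.na(didx), 0L, dose_sum$n_doses[didx])
  out$dose_ok <- dose_sum$dose_ok[didx]
  out$dose_bad <- dose_sum$dose_bad[didx]

  out$dnt <- as.numeric(difftime(out$needle, out$arrival, units = "mins"))
  out$otn <- as.numeric(difftime(out$needle, out$onset, units = "mins"))
  out
}

#' Evaluate the preprocessing rules on every trace
#'
#' Applies the nine-trace validation and derivation rules:
#' \enumerate{
#'   \item onset time and arrival time present (minute precision),
#'   \item onset strictly earlier than arrival,
#'   \item every order starts strictly later than arrival,
#'   \item arrival strictly earlier than neurology arrival (cooperative
#'     hospitals only),
#'   \item needle time = earliest thrombolytic order (derivation),
#'   \item neurology arrival = first order after admission (derivation),
#'   \item every rt-PA dose within 20--300 mg,
#'   \item door-to-needle time in (0, 360] min,
#'   \item onset-to-needle time in (0, 360] min.
#' }
#' Rules 7--9 apply only to patients with a needle time; violations are
#' verdicts, never errors.
#'
#' @param log A `careflow_log`.
#' @param config A [careflow_config()].
#' @return A `rule_report` tibble with one row per case and rule:
#'   `case_id, rule_id, applicable, passed, detail`.
#' @export
evaluate_rules <- function(log, config = careflow_config()) {
  stopifnot(is_careflow_log(log))
  config <- as_config(config)
  f <- case_facts(log, config)
  fmt_t <- function(t) ifelse(is.na(t), "missing",
                              format(t, "%Y-%m-%d %H:%M", tz = "UTC"))

  per_rule <- list(
    tibble(case_id = f$case_id, rule_id = 1L, applicable = TRUE,
           passed = !is.na(f$onset) & !is.na(f$arrival),
           detail = sprintf("onset %s, arrival %s", fmt_t(f$onset), fmt_t(f$arrival))),
    tibble(case_id = f$case_id, rule_id = 2L,
           applicable = !is.na(f$onset) & !is.na(f$arrival),
           passed = f$onset < f$arrival,
           detail = sprintf("onset %s vs arrival %s", fmt_t(f$onset), fmt_t(f$arrival))),
    tibble(case_id = f$case_id, rule_id = 3L,
           applicable = !is.na(f$arrival) & f$n_orders > 0L,
           passed = f$n_early_orders == 0L,
           detail = sprintf("%d order(s) not after arrival", f$n_early_orders)),
    tibble(case_id = f$case_id, rule_id = 4L,
           applicable = config$cooperative_hospital &
             !is.na(f$arrival) & !is.na(f$neurology),
           passed = f$arrival < f$neurology,
           detail = sprintf("arrival %s vs neurology %s",
                            fmt_t(f$arrival), fmt_t(f$neurology))),
    tibble(case_id = f$case_id, rule_id = 5L, applicable = !is.na(f$needle),
           passed = NA,
           detail = sprintf("needle time %s", fmt_t(f$needle))),
    tibble(case_id = f$case_id, rule_id = 6L,
           applicable = f$neurology_derived %in% TRUE,
           passed = NA,
           detail = sprintf("neurology arrival %s", fmt_t(f$neurology))),
    tibble(case_id = f$case_id, rule_id = 7L,
           applicable = !is.na(f$needle) & f$n_doses > 0L,
           passed = f$dose_ok %in% TRUE,
           detail = ifelse(f$dose_ok %in% TRUE | is.na(f$dose_ok),
                           "rt-PA dose in range",
                           sprintf("rt-PA dose out of range: %s mg", f$dose_bad))),
    tibble(case_id = f$case_id, rule_id = 8L,
           applicable = !is.na(f$needle) & !is.na(f$arrival),
           passed = f$dnt > config$dnt_range[1] & f$dnt <= config$dnt_range[2],
           detail = sprintf("door-to-needle %.0f min", f$dnt)),
    tibble(case_id = f$case_id, rule_id = 9L,
           applicable = !is.na(f$needle) & !is.na(f$onset),
           passed = f$otn > config$onset_needle_range[1] &
             f$otn <= config$onset_needle_range[2],
           detail = sprintf("onset-to-needle %.0f min", f$otn))
  )
  report <- bind_rows(per_rule)
  report$passed[!report$applicable] <- NA
  report <- arrange(report, .data$case_id, .data$rule_id)
  class(report) <- c("rule_report", class(report))
  report
}

#' Per-case acceptance summary of a rule report
#'
#' A trace is accepted iff every applicable validation rule passed
#' (derivation rules 5 and 6 never reject). In drop-event mode
#' (`strict_order_times = FALSE`) rule 3 does not reject either.
#'
#' @param report A `rule_report` from [evaluate_rules()].
#' @param config A [careflow_config()].
#' @return Tibble `case_id, accepted, failed_rules` (comma-joined rule ids).
#' @export
rule_summary <- function(report, config = careflow_config()) {
  config <- as_config(config)
  reject_ids <- validation_rule_ids()
  if (!config$strict_order_times) reject_ids <- setdiff(reject_ids, 3L)
  rel <- report[report$rule_id %in% validation_rule_ids() & report$applicable, ]
  fails <- rel[!rel$passed, ]
  base <- tibble(case_id = unique(report$case_id))
  failed_by_case <- summarise(group_by(fails, .data$case_id),
                              failed_rules = paste(sort(unique(.data$rule_id)),
                                                   collapse = ","),
                              rejected = any(.data$rule_id %in% reject_ids),
                              .groups = "drop")
  idx <- match(base$case_id, failed_by_case$case_id)
  tibble(case_id = base$case_id,
         accepted = ifelse(is.na(idx), TRUE, !failed_by_case$rejected[idx]),
         failed_rules = ifelse(is.na(idx), "", failed_by_case$failed_rules[idx]))
}

#' Filter an event log through the preprocessing rules
#'
#' Removes traces violating any applicable validation rule and reports every
#' trace's verdicts. Counts are conserved: accepted plus rejected equals the
#' input. Filtering an already-accepted log is the identity.
#'
#' @param log A `careflow_log`.
#' @param config A [careflow_config()].
#' @return List with `log` (accepted traces), `report` (full `rule_report`),
#'   and `summary` (per-case acceptance tibble).
#' @export
filter_log <- function(log, config = careflow_config()) {
  stopifnot(is_careflow_log(log))
  config <- as_config(config)
  if (n_traces(log) == 0L) {
    return(list(log = log,
                report = evaluate_rules(log, config),
                summary = tibble(case_id = character(), accepted = logical(),
                                 failed_rules = character())))
  }
  report <- evaluate_rules(log, config)
  summ <- rule_summary(report, config)
  clean <- filter_cases(log, summ$case_id[summ$accepted])
  if (!config$strict_order_times) {
    # drop-event mode: remove events of offending activities at/before arrival
    ev <- clean$events
    arr <- clean$patients$arrival_time[match(ev$case_id, clean$patients$case_id)]
    drop <- !is_artificial_code(ev$code) & !is.na(arr) & ev$timestamp <= arr
    clean$events <- ev[!drop, , drop = FALSE]
  }
  list(log = clean, report = report, summary = summ)
}

#' Write a rejection report CSV
#'
#' One row per failed applicable rule: `case_id,rule_id,detail`.
#'
#' @param report A `rule_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(report, path) {
  bad <- report[report$applicable & !is.na(report$passed) & !report$passed,
                c("case_id", "rule_id", "detail")]
  write.csv(as.data.frame(bad), path, row.names = FALSE)
  invisible(path)
}
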