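#' Analysis configuration
#'
#' Central bundle of tunable parameters shared by the rule engine, cohort
#' split, discovery, timeline and KPI modules.
#'
#' @param thrombolytic_codes Activity codes counted as thrombolytic drugs
#'   (rt-PA and urokinase by default). Matching is by code prefix, so an
#'   aggregated log whose events carry the parent class still matches.
#' @param imaging_codes Codes qualifying as brain imaging for
#'   imaging-to-needle time (head CT and head MRI by default).
#' @param cooperative_hospital Logical; enables rule 4 (arrival earlier than
#'   neurology-department arrival), which only applies to hospitals that
#'   transfer stroke patients to a neurology ward for thrombolysis.
#' @param derive_neurology Logical; when no explicit neurology arrival is
#'   recorded, derive it as the first order issued in the hospitalization
#'   stage (rule 6).
#' @param strict_order_times Logical; when `TRUE` a rule-3 violation (an
#'   order starting before hospital arrival) rejects the whole patient; when
#'   `FALSE` only the offending events are dropped.
#' @param dose_range rt-PA dose bounds in mg (rule 7).
#' @param dnt_range Door-to-needle bounds in minutes, `(low, high]` (rule 8).
#' @param onset_needle_range Onset-to-needle bounds in minutes (rule 9).
#' @param window_minutes Observation window after arrival for the
#'   non-thrombolysis cohort; 180 min = the thrombolysis cohort's 2-h median
#'   door-to-needle time plus the 1-h thrombolytic infusion.
#' @param dep_threshold Default dependency threshold for [discover()].
#' @param freq_ratio_threshold Default patient-frequency-ratio threshold.
#' @param anchor Anchor activity code for the timeline (hospital arrival).
#' @param kpi_references Named list of published reference values attached to
#'   KPI reports.
#' @return A `careflow_config` list.
#' @export
careflow_config <- function(thrombolytic_codes = c("C.D.3.1", "C.D.3.2"),
                            imaging_codes = c("C.O.2.1", "C.O.2.2"),
                            cooperative_hospital = FALSE,
                            derive_neurology = TRUE,
                            strict_order_times = TRUE,
                            dose_range = c(20, 300),
                            dnt_range = c(0, 360),
                            onset_needle_range = c(0, 360),
                            window_minutes = 180,
                            dep_threshold = 0.9,
                            freq_ratio_threshold = 0.05,
                            anchor = anchor_code(),
                            kpi_references = default_kpi_references()) {
  structure(list(thrombolytic_codes = thrombolytic_codes,
                 imaging_codes = imaging_codes,
                 cooperative_hospital = isTRUE(cooperative_hospital),
                 derive_neurology = isTRUE(derive_neurology),
                 strict_order_times = isTRUE(strict_order_times),
                 dose_range = dose_range,
                 dnt_range = dnt_range,
                 onset_needle_range = onset_needle_range,
                 window_minutes = window_minutes,
                 dep_threshold = dep_threshold,
                 freq_ratio_threshold = freq_ratio_threshold,
                 anchor = anchor,
                 kpi_references = kpi_references),
            class = "careflow_config")
}

#' Published reference values for the stroke KPIs
#'
#' Benchmarks quoted in the stroke quality-improvement literature:
#' SITS-MOST median door-to-needle time, the RCSN (Canada) median
#' imaging-to-needle time, the 75% within-60-min target of the Report on
#' Stroke Prevention and Treatment in China (2018), and the GWTG 2009 (US)
#' proportion of 2-h arrivals treated within 3 h.
#'
#' @return Named list of `list(value, source)` entries.
#' @export
default_kpi_references <- function() {
  list(
    dnt_median_minutes = list(value = 68, source = "SITS-MOST"),
    int_median_minutes = list(value = 31, source = "RCSN (Canada)"),
    pct_dnt_within_60 = list(
      value = 75,
      source = "Target, Report on Stroke Prevention and Treatment in China 2018"),
    pct_arrive2h_treated3h = list(value = 71.6, source = "GWTG 2009 (United States)")
  )
}

#' Read a configuration from a YAML file
#'
#' Any key accepted by [careflow_config()] may appear in the file; missing
#' keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `careflow_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(careflow_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(careflow_config, vals)
}

as_config <- function(config) {
  if (is.null(config)) careflow_config() else config
}

# does each code match the reference set, by equality or descent
code_in_set <- function(codes, set) {
  if (length(set) == 0L) return(rep(FALSE, length(codes)))
  hit <- rep(FALSE, length(codes))
  for (s in set) {
    hit <- hit | codes == s | startsWith(codes, paste0(s, "."))
  }
  hit
}

# artificial milestone events are not clinical orders
is_artificial_code <- function(codes) {
  codes == "C.A" | startsWith(codes, "C.A.")
}
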