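# --- synthetic stroke-pathway simulator --------------------------------------
#
# Reproducible event logs with known ground truth: pathway structure, timing
# distributions, cohort mix and planted rule violations. Service delays are
# log-normal (non-negative, right-skewed); timestamps are emitted at whole
# minutes, so ties occur and exercise the tie-breaking rules.

dist_fixed <- function(value) list(type = "fixed", value = value)
dist_lognormal <- function(median, sdlog) {
  list(type = "lognormal", median = median, sdlog = sdlog)
}

draw_dist <- function(d, n = 1L) {
  switch(d$type,
         fixed = rep(d$value, n),
         lognormal = rlnorm(n, meanlog = log(d$median), sdlog = d$sdlog),
         abort(sprintf("unknown distribution type '%s'", d$type)))
}

# rejection-sample a rounded draw until ok(x) holds
draw_ok <- function(d, ok) {
  for (i in 1:1000) {
    x <- round(draw_dist(d))
    if (ok(x)) return(x)
  }
  abort("distribution parameters incompatible with their constraints")
}

#' Default parameters of the stroke-pathway simulator
#'
#' The timing distributions of the packaged scenario. Door-to-needle time is
#' log-normal with median 117 min and a spread fixed so that 6.4% of the
#' mass lies within 60 min (`sdlog = log(60/117)/qnorm(0.064)`);
#' imaging-to-needle is log-normal with median 33 min; the neurology
#' transfer happens a few minutes before the needle (orders are issued in
#' batch on ward arrival), so the CT-to-neurology transit comes out near 30
#' min. Onset-to-arrival medians (80 min thrombolysis, 120 min conventional)
#' and the activity occurrence probabilities are plausible emergency-stroke
#' values chosen for the simulator; see the methods vignette.
#'
#' @return Parameter list consumed by [simulate_stroke_log()].
#' @export
stroke_sim_params <- function() {
  list(
    onset_to_arrival = list(
      thrombolysis = dist_lognormal(80, 0.5),
      non_thrombolysis = dist_lognormal(120, 0.5)),
    dnt = dist_lognormal(117, log(60 / 117) / qnorm(0.064)),
    int = dist_lognormal(33, 0.35),
    needle_delay = dist_lognormal(3, 0.5),
    ct_start = dist_lognormal(25, 0.4),
    transit = dist_lognormal(30, 0.3),
    ct_duration = 6,
    infusion_minutes = 60,
    dose_mg = c(50, 90),
    emergency = tibble(
      code = c("C.O.1.1", "C.O.3.1", "C.O.3.2", "C.O.3.3", "C.E.2.1"),
      name = c("ECG", "Blood routine test", "Coagulation function test",
               "Blood glucose test", "Consciousness evaluation"),
      prob = c(0.40, 0.90, 0.85, 0.70, 0.60),
      median = c(8.5, 15, 18, 12, 10),
      sdlog = c(0.4, 0.4, 0.4, 0.4, 0.5),
      duration = c(2, 25, 30, 10, 0)),
    hospitalization = tibble(
      code = c("C.P.1.1", "C.P.1.2", "C.E.1.1", "C.O.3.1", "C.O.3.4",
               "C.O.3.5", "C.D.4.1", "C.O.1.2", "C.O.2.3", "C.O.2.2", "C.D.5.1"),
      name = c("Blood pressure measurement", "Venous catheterization",
               "NIHSS assessment", "Blood routine test",
               "Detection of myocardial ischemia markers",
               "B-type natriuretic peptide", "Edaravone", "EEG", "TCCD",
               "Head MRI", "Olacetam"),
      prob = c(0.95, 0.85, 0.70, 0.60, 0.50, 0.40, 0.55, 0.30, 0.35, 0.30, 0.30),
      lo = c(1, 2, 2, 2, 3, 3, 4, 60, 60, 60, 10),
      hi = c(3, 6, 8, 8, 10, 10, 12, 150, 150, 160, 30),
      duration = c(0, 0, 0, 25, 35, 35, 60, 30, 25, 30, 60),
      cohorts = c("both", "both", "both", "both", "thrombolysis",
                  "thrombolysis", "both", "non_thrombolysis",
                  "non_thrombolysis", "non_thrombolysis", "non_thrombolysis"))
  )
}

# accumulator for the start/complete rows of one patient's activities;
# duration <= 0 means only one instant was recorded, so the activity starts
# when it finishes
new_trace_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$code <- character(); env$name <- character(); env$offset <- numeric()
  env$stage <- character(); env$dose <- numeric()
  env
}

add_activity <- function(tb, code, name, start_off, duration, stage,
                         dose = NA_real_) {
  end_off <- if (duration <= 0) start_off else start_off + duration
  tb$code <- c(tb$code, code, code)
  tb$name <- c(tb$name, name, name)
  tb$offset <- c(tb$offset, start_off, end_off)
  tb$stage <- c(tb$stage, stage, stage)
  tb$dose <- c(tb$dose, dose, NA_real_)
  invisible(tb)
}

simulate_patient <- function(cohort, p) {
  tb <- new_trace_builder()
  if (cohort == "thrombolysis") {
    # upper truncations keep the whole cohort rule-8/9 compliant (the study
    # population passed the preprocessing rules); they trim ~1% of the mass
    dnt <- draw_ok(p$dnt, function(x) x >= 30 && x <= 320)
    int <- draw_ok(p$int, function(x) x >= 5 && x <= dnt - 15)
    delay <- max(1, min(int - 2, round(draw_dist(p$needle_delay))))
    ota <- draw_ok(p$onset_to_arrival$thrombolysis,
                   function(x) x >= 10 && x + dnt <= 350)
    ct_complete <- dnt - int
    ct_start <- ct_complete - p$ct_duration
    neurology <- dnt - delay
    add_activity(tb, "C.O.2.1", "Head CT", ct_start, ct_complete - ct_start,
                 "emergency")
    dose <- round(runif(1, p$dose_mg[1], p$dose_mg[2]))
    add_activity(tb, "C.D.3.1", "rt-PA", dnt, p$infusion_minutes,
                 "hospitalization", dose)
    int_true <- int
  } else {
    ota <- draw_ok(p$onset_to_arrival$non_thrombolysis, function(x) x >= 10)
    ct_start <- max(2, round(draw_dist(p$ct_start)))
    ct_complete <- ct_start + p$ct_duration
    neurology <- ct_complete + max(5, round(draw_dist(p$transit)))
    dnt <- NA_real_
    int_true <- NA_real_
    dose <- NA_real_
    add_activity(tb, "C.O.2.1", "Head CT", ct_start, p$ct_duration, "emergency")
  }
  em <- p$emergency
  for (i in seq_len(nrow(em))) {
    if (runif(1) < em$prob[i]) {
      t <- max(1, round(rlnorm(1, log(em$median[i]), em$sdlog[i])))
      t <- min(t, max(1, neurology - 2))
      add_activity(tb, em$code[i], em$name[i], t, em$duration[i], "emergency")
    }
  }
  hs <- p$hospitalization
  hs <- hs[hs$cohorts == "both" | hs$cohorts == cohort, , drop = FALSE]
  for (i in seq_len(nrow(hs))) {
    if (runif(1) < hs$prob[i]) {
      t <- neurology + sample(hs$lo[i]:hs$hi[i], 1)
      add_activity(tb, hs$code[i], hs$name[i], t, hs$duration[i],
                   "hospitalization")
    }
  }
  list(tb = tb, ota = ota, neurology = neurology, dnt = dnt, int = int_true,
       dose = dose, cohort = cohort)
}

# assemble per-patient trace builders into one events/patients/truth bundle
assemble_sim <- function(ids, arrivals, drawn) {
  n_ev <- vapply(drawn, function(d) length(d$tb$code), integer(1))
  rep_id <- rep(ids, times = n_ev)
  rep_arr <- rep(arrivals, times = n_ev)
  offsets <- unlist(lapply(drawn, function(d) d$tb$offset))
  events <- tibble(
    case_id = rep_id,
    code = unlist(lapply(drawn, function(d) d$tb$code)),
    name = unlist(lapply(drawn, function(d) d$tb$name)),
    lifecycle = rep(c("start", "complete"), length.out = length(rep_id)),
    timestamp = rep_arr + 60 * offsets,
    stage = unlist(lapply(drawn, function(d) d$tb$stage)),
    dose_mg = unlist(lapply(drawn, function(d) d$tb$dose)))
  ota <- vapply(drawn, `[[`, numeric(1), "ota")
  neurology <- vapply(drawn, `[[`, numeric(1), "neurology")
  dnt <- vapply(drawn, `[[`, numeric(1), "dnt")
  patients <- tibble(case_id = ids,
                     onset_time = arrivals - 60 * ota,
                     arrival_time = arrivals,
                     neurology_arrival_time = arrivals + 60 * neurology)
  truth <- tibble(case_id = ids,
                  cohort = vapply(drawn, `[[`, character(1), "cohort"),
                  onset_to_arrival = ota, dnt = dnt,
                  int = vapply(drawn, `[[`, numeric(1), "int"),
                  onset_to_needle = ifelse(is.na(dnt), NA_real_, ota + dnt),
                  dose_mg = vapply(drawn, `[[`, numeric(1), "dose"),
                  planted_rules = "")
  list(events = events, patients = patients, truth = truth)
}

# mutate one generated case so it violates exactly the planted rule (plus
# logically implied ones: DNT > 360 forces onset-to-needle > 360)
plant_violation <- function(sim, cid, rule) {
  pat <- sim$patients$case_id == cid
  tru <- sim$truth$case_id == cid
  arrival <- sim$patients$arrival_time[pat]
  mark <- function(ids) {
    sim$truth$planted_rules[tru] <<- paste(ids, collapse = ",")
  }
  if (rule == 1L) {
    sim$patients$onset_time[pat] <- NA
    sim$truth$onset_to_arrival[tru] <- NA
    sim$truth$onset_to_needle[tru] <- NA
    mark(1L)
  } else if (rule == 2L) {
    sim$patients$onset_time[pat] <- arrival + 10 * 60
    sim$truth$onset_to_arrival[tru] <- -10
    if (!is.na(sim$truth$dnt[tru])) {
      sim$truth$onset_to_needle[tru] <- sim$truth$dnt[tru] - 10
    }
    mark(2L)
  } else if (rule == 3L) {
    ev <- sim$events
    cand <- which(ev$case_id == cid & ev$lifecycle == "start" &
                    !is_artificial_code(ev$code))
    first <- cand[which.min(ev$timestamp[cand])]
    sim$events$timestamp[first] <- arrival - 5 * 60
    mark(3L)
  } else if (rule == 4L) {
    sim$patients$neurology_arrival_time[pat] <- arrival - 10 * 60
    mark(4L)
  } else if (rule == 7L) {
    ev <- sim$events
    hit <- ev$case_id == cid & ev$lifecycle == "start" & ev$code == rt_pa_code()
    sim$events$dose_mg[hit] <- 10
    sim$truth$dose_mg[tru] <- 10
    mark(7L)
  } else if (rule == 8L) {
    ev <- sim$events
    hit <- ev$case_id == cid & ev$code == rt_pa_code()
    shift <- (390 - sim$truth$dnt[tru]) * 60
    sim$events$timestamp[hit] <- ev$timestamp[hit] + shift
    sim$truth$dnt[tru] <- 390
    sim$truth$onset_to_needle[tru] <- sim$truth$onset_to_arrival[tru] + 390
    mark(c(8L, 9L))  # onset < arrival forces onset-to-needle > 360 too
  } else if (rule == 9L) {
    new_onset <- arrival + (sim$truth$dnt[tru] - 400) * 60
    sim$patients$onset_time[pat] <- new_onset
    sim$truth$onset_to_arrival[tru] <- 400 - sim$truth$dnt[tru]
    sim$truth$onset_to_needle[tru] <- 400
    mark(9L)
  } else {
    abort(sprintf("cannot plant a violation of rule %d", rule))
  }
  sim
}

#' Simulate a two-cohort acute-stroke event log
#'
#' The packaged default scenario: 125 thrombolysed and 295 conventionally
#' treated patients travel the onset, arrival, emergency work-up (ECG, head
#' CT, laboratory tests), neurology transfer, nursing/evaluation and, for
#' the thrombolysis cohort, rt-PA pathway, with log-normal service delays
#' (see [stroke_sim_params()]), repeated laboratory tests across the two
#' stages, and whole-minute timestamps. Ground truth records every patient's
#' true door-to-needle, imaging-to-needle and onset-to-arrival minutes plus
#' any planted rule violations. The same seed yields an identical log.
#'
#' @param n_thrombolysis,n_non_thrombolysis Cohort sizes.
#' @param seed Mandatory integer seed.
#' @param violations Named list, rule id to count of traces to corrupt, e.g.
#'   `list("2" = 5)`. Rules 7-9 need thrombolysed patients. A rule-8 plant
#'   (door-to-needle over 360 min) necessarily also violates rule 9 and is
#'   recorded as `"8,9"` in the ground truth.
#' @param params Timing parameters, see [stroke_sim_params()].
#' @param origin Date-time of the first arrival; patients arrive on
#'   consecutive days.
#' @return List with `log` (a `careflow_log`) and `truth` (tibble
#'   `case_id, cohort, onset_to_arrival, dnt, int, onset_to_needle, dose_mg,
#'   planted_rules`).
#' @export
simulate_stroke_log <- function(n_thrombolysis = 125, n_non_thrombolysis = 295,
                                seed, violations = list(),
                                params = stroke_sim_params(),
                                origin = "2019-01-01 00:00:00") {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(as.integer(seed))
  origin <- as.POSIXct(origin, tz = "UTC")
  n_total <- n_thrombolysis + n_non_thrombolysis
  cohorts <- c(rep("thrombolysis", n_thrombolysis),
               rep("non_thrombolysis", n_non_thrombolysis))
  ids <- sprintf("P%04d", seq_len(n_total))
  arrivals <- origin
  drawn <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    arrivals[i] <- origin + 86400 * (i - 1) + 60 * sample(360:1200, 1)
    drawn[[i]] <- simulate_patient(cohorts[i], params)
  }
  sim <- assemble_sim(ids, arrivals, drawn)

  if (length(violations) > 0L) {
    thromb_pool <- rev(sim$truth$case_id[sim$truth$cohort == "thrombolysis"])
    conv_pool <- rev(sim$truth$case_id[sim$truth$cohort == "non_thrombolysis"])
    take <- function(pool_pref) {
      for (pool_name in pool_pref) {
        pool <- if (pool_name == "thromb") thromb_pool else conv_pool
        if (length(pool) > 0L) {
          id <- pool[1]
          thromb_pool <<- setdiff(thromb_pool, id)
          conv_pool <<- setdiff(conv_pool, id)
          return(id)
        }
      }
      abort("not enough unviolated traces to plant all requested violations")
    }
    for (rule_chr in names(violations)) {
      rule <- as.integer(rule_chr)
      pref <- if (rule %in% c(7L, 8L, 9L)) "thromb" else c("conv", "thromb")
      for (k in seq_len(violations[[rule_chr]])) {
        sim <- plant_violation(sim, take(pref), rule)
      }
    }
  }
  log <- event_log(sim$events, sim$patients,
                   metadata = list(generator = "simulate_stroke_log", seed = seed))
  list(log = log, truth = sim$truth)
}

#' Define a pathway template for controlled simulation
#'
#' A simple stage-based template for experiments with known timing: each
#' stage is an activity with an occurrence probability and an offset
#' distribution in minutes from hospital arrival (`offset_sdlog = 0` makes
#' the offset deterministic).
#'
#' @param label Template name.
#' @param stages Tibble with columns `code, name, prob, offset_median,
#'   offset_sdlog, duration, stage`.
#' @param onset_to_arrival Onset-to-arrival distribution
#'   ([dist_fixed()]/[dist_lognormal()]-style list).
#' @param neurology_offset Optional neurology-arrival offset distribution;
#'   `NULL` omits the attribute.
#' @return A `pathway_template` list.
#' @export
pathway_template <- function(label, stages,
                             onset_to_arrival = dist_fixed(60),
                             neurology_offset = NULL) {
  stopifnot(all(c("code", "name", "prob", "offset_median", "offset_sdlog",
                  "duration", "stage") %in% names(stages)))
  if (any(stages$prob < 0 | stages$prob > 1)) {
    abort("stage probabilities must lie in [0, 1]")
  }
  structure(list(label = label, stages = as_tibble(stages),
                 onset_to_arrival = onset_to_arrival,
                 neurology_offset = neurology_offset),
            class = "pathway_template")
}

#' Simulate an event log from a pathway template
#'
#' @param template A [pathway_template()].
#' @param n Number of patients.
#' @param seed Mandatory integer seed.
#' @param origin Date-time of the first arrival.
#' @return List with `log` and `truth` (per-patient stage offsets in
#'   long form: `case_id, code, offset`).
#' @export
simulate_pathway_log <- function(template, n, seed,
                                 origin = "2019-01-01 00:00:00") {
  stopifnot(inherits(template, "pathway_template"))
  if (missing(seed)) abort("seed is mandatory")
  set.seed(as.integer(seed))
  origin <- as.POSIXct(origin, tz = "UTC")
  st <- template$stages
  ids <- sprintf("S%04d", seq_len(n))
  arrivals <- origin
  drawn <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    arrivals[i] <- origin + 86400 * (i - 1) + 60 * sample(360:1200, 1)
    ota <- max(1, round(draw_dist(template$onset_to_arrival)))
    neuro <- if (is.null(template$neurology_offset)) NA_real_ else
      round(draw_dist(template$neurology_offset))
    tb <- new_trace_builder()
    offs <- numeric(0)
    codes <- character(0)
    for (s in seq_len(nrow(st))) {
      if (runif(1) < st$prob[s]) {
        t <- if (st$offset_sdlog[s] == 0) st$offset_median[s] else
          max(1, round(rlnorm(1, log(st$offset_median[s]), st$offset_sdlog[s])))
        add_activity(tb, st$code[s], st$name[s], t, st$duration[s], st$stage[s])
        offs <- c(offs, t)
        codes <- c(codes, st$code[s])
      }
    }
    drawn[[i]] <- list(tb = tb, ota = ota, neurology = neuro,
                       dnt = NA_real_, int = NA_real_, dose = NA_real_,
                       cohort = template$label)
    truth[[i]] <- tibble(case_id = ids[i], code = codes, offset = offs)
  }
  sim <- assemble_sim(ids, arrivals, drawn)
  patients <- sim$patients
  if (is.null(template$neurology_offset)) {
    patients$neurology_arrival_time <- as.POSIXct(NA, tz = "UTC")
  }
  log <- event_log(sim$events, patients,
                   metadata = list(generator = template$label, seed = seed))
  list(log = log, truth = bind_rows(truth))
}

#' The noise-free linear stroke pathway template
#'
#' Onset 60 min before arrival, head CT at 20 min, neurology arrival at 50
#' min, rt-PA at 80 min, every stage deterministic and present in every
#' trace. Discovery at permissive thresholds recovers exactly this chain.
#'
#' @return A `pathway_template`.
#' @export
linear_stroke_template <- function() {
  pathway_template(
    "linear_stroke",
    stages = tibble(
      code = c("C.O.2.1", "C.D.3.1"),
      name = c("Head CT", "rt-PA"),
      prob = c(1, 1),
      offset_median = c(20, 80),
      offset_sdlog = c(0, 0),
      duration = c(0, 0),
      stage = c("emergency", "hospitalization")),
    onset_to_arrival = dist_fixed(60),
    neurology_offset = dist_fixed(50))
}
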