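rules_cfg <- function(...) careflow_config(cooperative_hospital = TRUE, ...)

test_that("needle time is the earliest thrombolytic order", {
  arr <- t0()
  ev <- tibble::tibble(
    case_id = "P1",
    code = c("C.D.3.1", "C.D.3.2", "C.O.1.1"),
    name = c("rt-PA", "Urokinase", "ECG"),
    lifecycle = "start",
    timestamp = arr + 60 * c(30, 50, 10))
  log <- event_log(ev)
  out <- derive_needle_time(log)
  expect_equal(out$needle_time, arr + 60 * 30)  # 10:30 beats 10:50

  # a single urokinase order supplies its own start time
  solo <- event_log(ev[2, ])
  expect_equal(derive_needle_time(solo)$needle_time, arr + 60 * 50)

  # no thrombolytic order: absent, not an error
  none <- event_log(ev[3, ])
  expect_true(is.na(derive_needle_time(none)$needle_time))
})

test_that("neurology arrival derives from the first admission order, with an
           explicit attribute taking precedence", {
  arr <- t0()
  ev <- tibble::tibble(
    case_id = "P1",
    code = c("C.O.1.1", "C.P.1.1", "C.E.1.1"),
    name = c("ECG", "BP", "NIHSS"),
    lifecycle = "start",
    timestamp = arr + 60 * c(10, 65, 70),
    stage = c("emergency", "hospitalization", "hospitalization"))
  log <- event_log(ev)
  out <- derive_neurology_arrival(log)
  expect_equal(out$neurology_arrival_time, arr + 60 * 65)
  expect_true(out$derived)

  # emergency-only trace: absent
  em <- event_log(ev[1, ])
  expect_true(is.na(derive_neurology_arrival(em)$neurology_arrival_time))

  # explicit attribute wins over the derivation
  pats <- tibble::tibble(case_id = "P1", neurology_arrival_time = arr + 60 * 58)
  log2 <- event_log(ev, pats)
  out2 <- derive_neurology_arrival(log2)
  expect_equal(out2$neurology_arrival_time, arr + 60 * 58)
  expect_false(out2$derived)
})

test_that("individual rule verdicts match hand-built violations", {
  base <- tiny_clinical_log()
  report_of <- function(log) evaluate_rules(log, rules_cfg())
  failed_ids <- function(rep) {
    rep$rule_id[rep$applicable & !is.na(rep$passed) & !rep$passed]
  }

  expect_equal(failed_ids(report_of(base)), integer(0))

  # onset after arrival (onset 09:00, arrival 08:30 pattern)
  late_onset <- base
  late_onset$patients$onset_time <- base$patients$arrival_time + 30 * 60
  expect_equal(failed_ids(report_of(late_onset)), 2L)

  # missing onset: only rule 1 (rules 2 and 9 become inapplicable)
  no_onset <- base
  no_onset$patients$onset_time <- as.POSIXct(NA, tz = "UTC")
  expect_equal(failed_ids(report_of(no_onset)), 1L)

  # an order starting before arrival
  early_order <- base
  i <- which(early_order$events$code == "C.O.2.1" &
               early_order$events$lifecycle == "start")
  early_order$events$timestamp[i] <- base$patients$arrival_time - 5 * 60
  early_order$events <- early_order$events[order(early_order$events$timestamp), ]
  expect_equal(failed_ids(report_of(early_order)), 3L)

  # neurology arrival before hospital arrival (cooperative hospitals)
  bad_neuro <- base
  bad_neuro$patients$neurology_arrival_time <- base$patients$arrival_time - 10 * 60
  expect_equal(failed_ids(report_of(bad_neuro)), 4L)
  # ... not applicable outside cooperative hospitals
  rep_nc <- evaluate_rules(bad_neuro, careflow_config())
  expect_false(rep_nc$applicable[rep_nc$rule_id == 4])

  # rt-PA dose of 10 mg breaches the 20-300 mg range
  low_dose <- base
  low_dose$events$dose_mg[low_dose$events$code == "C.D.3.1" &
                            low_dose$events$lifecycle == "start"] <- 10
  expect_equal(failed_ids(report_of(low_dose)), 7L)

  # door-to-needle of 390 min breaches (0, 360]; onset-to-needle follows
  slow <- base
  j <- slow$events$code == "C.D.3.1"
  slow$events$timestamp[j] <- slow$events$timestamp[j] + (390 - 117) * 60
  expect_equal(failed_ids(report_of(slow)), c(8L, 9L))

  # onset-to-needle alone can exceed 360 with a compliant DNT
  far_onset <- base
  far_onset$patients$onset_time <-
    base$patients$arrival_time + (117 - 400) * 60
  expect_equal(failed_ids(report_of(far_onset)), 9L)
})

test_that("filter_log partitions traces, conserves counts and is idempotent", {
  sim <- simulate_stroke_log(8, 12, seed = 31,
                             violations = list("1" = 2, "2" = 2, "7" = 1))
  res <- filter_log(sim$log, rules_cfg())
  expect_equal(n_traces(res$log) + sum(!res$summary$accepted), n_traces(sim$log))
  expect_equal(sum(!res$summary$accepted), 5)
  # every input trace is reported on
  expect_setequal(res$summary$case_id, case_ids(sim$log))
  # the failed rule ids equal the planted ones exactly
  planted <- sim$truth[sim$truth$planted_rules != "", ]
  got <- res$summary[match(planted$case_id, res$summary$case_id), ]
  expect_equal(got$failed_rules, planted$planted_rules)
  # an all-compliant log comes back unchanged, and refiltering changes nothing
  res2 <- filter_log(res$log, rules_cfg())
  expect_true(logs_equal(res2$log, res$log))
  expect_true(all(res2$summary$accepted))
})

test_that("drop-event mode keeps the patient but sheds pre-arrival orders", {
  sim <- simulate_stroke_log(3, 3, seed = 7, violations = list("3" = 2))
  cfg <- rules_cfg(strict_order_times = FALSE)
  res <- filter_log(sim$log, cfg)
  expect_equal(n_traces(res$log), 6)  # nobody rejected
  arr <- res$log$patients$arrival_time[
    match(res$log$events$case_id, res$log$patients$case_id)]
  starts <- res$log$events$lifecycle == "start" &
    !startsWith(res$log$events$code, "C.A")
  expect_true(all(res$log$events$timestamp[starts] > arr[starts]))
})

test_that("accepted traces satisfy the onset < arrival < order-start chain", {
  sim <- simulate_stroke_log(10, 10, seed = 13)
  res <- filter_log(sim$log, rules_cfg())
  log <- res$log
  onset <- log$patients$onset_time[match(log$events$case_id, log$patients$case_id)]
  starts <- log$events$lifecycle == "start" & !startsWith(log$events$code, "C.A")
  # rules 2 and 3 jointly imply every order starts strictly after onset
  expect_true(all(log$events$timestamp[starts] > onset[starts]))
})

test_that("the rejection report lists one row per failed applicable rule", {
  sim <- simulate_stroke_log(4, 4, seed = 17, violations = list("2" = 1, "8" = 1))
  res <- filter_log(sim$log, rules_cfg())
  path <- withr::local_tempfile(fileext = ".csv")
  write_rejection_report(res$report, path)
  rej <- read.csv(path)
  expect_setequal(names(rej), c("case_id", "rule_id", "detail"))
  expect_equal(sort(unique(rej$rule_id)), c(2, 8, 9))
})
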