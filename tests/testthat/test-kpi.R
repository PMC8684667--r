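test_that("door-to-needle is needle minus arrival, absent without a needle", {
  log <- tiny_clinical_log()  # arrival 08:00-style, needle 117 min later
  dnt <- door_to_needle(log)
  expect_equal(dnt$dnt_minutes, 117)
  no_needle <- event_log(log$events[log$events$code != "C.D.3.1", ],
                         log$patients)
  expect_true(is.na(door_to_needle(no_needle)$dnt_minutes))
})

test_that("imaging-to-needle uses the last qualifying imaging before needle", {
  log <- tiny_clinical_log()  # head CT completes at 84, needle at 117
  int <- imaging_to_needle(log)
  expect_equal(int$int_minutes, 33)

  # a second, later CT before the needle supersedes the first
  extra <- log
  extra$events <- dplyr::bind_rows(
    extra$events,
    tibble::tibble(case_id = "P1", code = "C.O.2.1", name = "Head CT",
                   lifecycle = "complete",
                   timestamp = log$patients$arrival_time + 60 * 100,
                   stage = "emergency", dose_mg = NA_real_))
  extra$events <- extra$events[order(extra$events$timestamp), ]
  expect_equal(imaging_to_needle(extra)$int_minutes, 17)
  # brute-force scan over qualifying completions agrees
  ev <- extra$events
  compl <- ev$timestamp[ev$code == "C.O.2.1" & ev$lifecycle == "complete"]
  needle <- derive_needle_time(extra)$needle_time
  expect_equal(imaging_to_needle(extra)$int_minutes,
               as.numeric(difftime(needle, max(compl[compl <= needle]),
                                   units = "mins")))
  # first-imaging mode remains available
  expect_equal(imaging_to_needle(extra, mode = "first")$int_minutes, 33)

  # imaging only after the needle: absent
  post <- log
  post$events$timestamp[post$events$code == "C.O.2.1"] <-
    log$patients$arrival_time + 60 * c(150, 156)
  post$events <- post$events[order(post$events$timestamp), ]
  expect_true(is.na(imaging_to_needle(post)$int_minutes))
})

test_that("proportion_within is an inclusive percentage, monotone in the bound", {
  expect_equal(proportion_within(c(50, 70, 55, 90), 60), 50)
  expect_equal(proportion_within(c(70, 90), 60), 0)
  expect_equal(proportion_within(c(60), 60), 100)  # inclusive bound
  expect_true(is.na(proportion_within(numeric(0), 60)))
  vals <- c(10, 45, 61, 200, 360)
  p <- vapply(c(0, 30, 60, 120, 400), proportion_within, numeric(1),
              values = vals)
  expect_false(is.unsorted(p))
})

test_that("the 2h-arrival/3h-treatment rate filters on both windows", {
  arr <- t0()
  mk <- function(cid, o2a, dnt = NA) {
    events <- if (is.na(dnt)) {
      tibble::tibble(case_id = cid, code = "C.O.1.1", name = "ECG",
                     lifecycle = "complete", timestamp = arr + 60 * 5)
    } else {
      tibble::tibble(case_id = cid, code = "C.D.3.1", name = "rt-PA",
                     lifecycle = "start", timestamp = arr + 60 * dnt)
    }
    patients <- tibble::tibble(case_id = cid, onset_time = arr - 60 * o2a,
                               arrival_time = arr)
    list(events = events, patients = patients)
  }
  parts <- list(mk("A", 90, 80),    # 90 + 80 = 170 <= 180: treated in time
                mk("B", 90, 120),   # 210 > 180: in denominator only
                mk("C", 150, 20),   # arrived after 2 h: excluded entirely
                mk("D", 60))        # early arrival, never treated
  log <- event_log(dplyr::bind_rows(lapply(parts, `[[`, "events")),
                   dplyr::bind_rows(lapply(parts, `[[`, "patients")))
  # denominator {A, B, D}, numerator {A}
  expect_equal(arrive2h_treated3h(log), 100 / 3)
  # brute-force double filter agrees
  o2a <- c(90, 90, 150, 60); o2n <- c(170, 210, NA, NA)
  expect_equal(arrive2h_treated3h(log),
               100 * sum(o2a <= 120 & !is.na(o2n) & o2n <= 180) / sum(o2a <= 120))
  # boundary: a single 2h-150min arrival leaves an empty denominator
  solo <- event_log(parts[[3]]$events, parts[[3]]$patients)
  expect_true(is.na(arrive2h_treated3h(solo)))
})

test_that("DNT decomposes into INT plus door-to-imaging for every patient", {
  sim <- simulate_stroke_log(40, 0, seed = 61)
  log <- sim$log
  dnt <- door_to_needle(log)
  int <- imaging_to_needle(log)
  arr <- log$patients$arrival_time[match(int$case_id, log$patients$case_id)]
  d2i <- as.numeric(difftime(int$imaging_completion, arr, units = "mins"))
  expect_equal(dnt$dnt_minutes, int$int_minutes + d2i)
})

test_that("KPI medians recover the generator's ground truth", {
  sim <- simulate_stroke_log(60, 0, seed = 67)
  dnt <- door_to_needle(sim$log)
  expect_equal(sort(dnt$dnt_minutes), sort(sim$truth$dnt))
  expect_equal(median(dnt$dnt_minutes), median(sim$truth$dnt))
  int <- imaging_to_needle(sim$log)
  expect_equal(sort(int$int_minutes), sort(sim$truth$int))
})

test_that("KPI reports assemble per cohort, with references attached", {
  sim <- simulate_stroke_log(10, 15, seed = 71)
  co <- split_cohorts(sim$log)
  rep_t <- kpi_report(co$thrombolysis)
  expect_equal(rep_t$n, 10)
  expect_false(is.na(rep_t$dnt_median))
  expect_false(is.na(rep_t$int_median))
  expect_equal(rep_t$references$pct_dnt_within_60$value, 75)
  # cohort without thrombolysis: needle KPIs absent, report still produced
  rep_n <- kpi_report(co$non_thrombolysis)
  expect_equal(rep_n$n, 15)
  expect_true(is.na(rep_n$dnt_median))
  expect_true(is.na(rep_n$int_median))
  # KPIs survive a global time translation
  shifted <- sim$log
  shifted$events$timestamp <- shifted$events$timestamp + 365 * 86400
  for (col in c("onset_time", "arrival_time", "neurology_arrival_time")) {
    shifted$patients[[col]] <- shifted$patients[[col]] + 365 * 86400
  }
  rep_s <- kpi_report(split_cohorts(shifted)$thrombolysis)
  expect_equal(rep_s$dnt_median, rep_t$dnt_median)
  expect_equal(rep_s$pct_dnt_within_60, rep_t$pct_dnt_within_60)

  path <- withr::local_tempfile(fileext = ".json")
  write_kpi_report(list(rep_t, rep_n), path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(payload$cohorts$cohort, c("thrombolysis", "non_thrombolysis"))
  expect_equal(payload$cohorts$dnt_median_minutes[1], rep_t$dnt_median)
})
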