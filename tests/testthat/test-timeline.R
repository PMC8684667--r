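fixed_offset_cohort <- function(n = 12, seed = 5) {
  stages <- tibble::tibble(
    code = c("C.O.1.1", "C.O.2.1", "C.D.3.1"),
    name = c("ECG", "Head CT", "rt-PA"),
    prob = 1, offset_median = c(9, 20, 80), offset_sdlog = 0,
    duration = 0, stage = c("emergency", "emergency", "hospitalization"))
  tpl <- pathway_template("fixed_offsets", stages,
                          onset_to_arrival = dist_fixed(60),
                          neurology_offset = dist_fixed(50))
  sim <- simulate_pathway_log(tpl, n = n, seed = seed)
  add_artificial_events(sim$log)
}

test_that("relative minutes are signed offsets from the anchor", {
  log <- fixed_offset_cohort(n = 3)
  offs <- relative_minutes(log)
  expect_equal(unique(offs$minutes[offs$code == "C.A.1"]), -60)  # onset negative
  expect_equal(unique(offs$minutes[offs$code == "C.A.2"]), 0)    # anchor at zero
  expect_equal(unique(offs$minutes[offs$code == "C.O.1.1"]), 9)
  expect_equal(unique(offs$minutes[offs$code == "C.D.3.1"]), 80)

  # a missing or duplicated anchor names the offending case
  noanchor <- log
  noanchor$events <- noanchor$events[noanchor$events$code != "C.A.2" |
                                       noanchor$events$case_id != "S0001", ]
  expect_error(relative_minutes(noanchor), "S0001")
})

test_that("activity stats carry patient counts, ratios and order statistics", {
  log <- fixed_offset_cohort(n = 10)
  # drop ECG from six traces to get a 0.40 frequency ratio
  drop_ids <- sprintf("S%04d", 1:6)
  log$events <- log$events[!(log$events$code == "C.O.1.1" &
                               log$events$case_id %in% drop_ids), ]
  stats <- compute_stats(log, ontology = stroke_ontology())
  ecg <- stats[stats$code == "C.O.1.1", ]
  expect_equal(ecg$n_patients, 4)
  expect_equal(ecg$freq_ratio, 0.40)
  expect_equal(ecg$median_minutes, 9)
  expect_equal(ecg$category, "Observation")
  anchor <- stats[stats$code == "C.A.2", ]
  expect_equal(anchor$freq_ratio, 1)
  expect_equal(anchor$median_minutes, 0)
  expect_true(all(stats$min_minutes <= stats$median_minutes &
                    stats$median_minutes <= stats$max_minutes))
})

test_that("the median of an even-length offset list averages the middle pair", {
  arr <- t0()
  events <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(case_id = sprintf("P%d", i),
                   code = c("C.A.2", "C.O.1.1"),
                   name = c("Arrive at hospital", "ECG"),
                   lifecycle = "complete",
                   timestamp = arr + 86400 * i + 60 * c(0, c(5, 8, 9, 12)[i]))
  }))
  stats <- compute_stats(event_log(events))
  expect_equal(stats$median_minutes[stats$code == "C.O.1.1"], 8.5)
})

test_that("stats equal a brute-force recomputation on random cohorts", {
  sim <- simulate_stroke_log(12, 0, seed = 57)
  log <- add_artificial_events(sim$log)
  stats <- compute_stats(log)
  ev <- log$events[log$events$lifecycle == "complete", ]
  arr <- log$patients$arrival_time[match(ev$case_id, log$patients$case_id)]
  off <- round(as.numeric(difftime(ev$timestamp, arr, units = "mins")), 1)
  for (code in unique(ev$code)) {
    sel <- ev$code == code
    # brute force: first occurrence per patient, then pooled order stats
    firsts <- vapply(split(off[sel], ev$case_id[sel]), min, numeric(1))
    row <- stats[stats$code == code, ]
    expect_equal(row$n_patients, length(firsts))
    expect_equal(row$freq_ratio, length(firsts) / n_traces(log))
    expect_equal(row$min_minutes, min(firsts))
    expect_equal(row$median_minutes, median(firsts))
    expect_equal(row$max_minutes, max(firsts))
  }
})

test_that("repeated activities can pool all occurrences on request", {
  arr <- t0()
  ev <- tibble::tibble(case_id = "P1",
                       code = c("C.A.2", "C.O.3.1", "C.O.3.1"),
                       name = c("Arrive at hospital", "Lab", "Lab"),
                       lifecycle = "complete",
                       timestamp = arr + 60 * c(0, 10, 50))
  log <- event_log(ev)
  first <- compute_stats(log, occurrences = "first")
  all_occ <- compute_stats(log, occurrences = "all")
  expect_equal(first$median_minutes[first$code == "C.O.3.1"], 10)
  expect_equal(all_occ$median_minutes[all_occ$code == "C.O.3.1"], 30)
  expect_equal(all_occ$n_events[all_occ$code == "C.O.3.1"], 2)
  # event-frequency ratio variant
  evr <- compute_stats(log, freq_mode = "events")
  expect_equal(evr$freq_ratio[evr$code == "C.O.3.1"], 2)
})

test_that("enhancement sets display times, labels and chronological order", {
  log <- fixed_offset_cohort(n = 10)
  drop_ids <- sprintf("S%04d", 1:6)
  log$events <- log$events[!(log$events$code == "C.O.1.1" &
                               log$events$case_id %in% drop_ids), ]
  stats <- compute_stats(log, ontology = stroke_ontology())
  # keep every activity, including the 0.40-ratio ECG
  g <- discover(log, 0, 0)
  timed <- enhance(g, stats)
  ecg_label <- timed$nodes$label[timed$nodes$code == "C.O.1.1"]
  expect_equal(ecg_label, "ECG(0.40,9.0)")
  expect_equal(timed$nodes$display_time[timed$nodes$code == "C.A.2"], 0)
  expect_false(is.unsorted(timed$nodes$display_time))
  # display times follow the generating offsets exactly
  want <- c("C.A.1" = -60, "C.A.2" = 0, "C.O.1.1" = 9, "C.O.2.1" = 20,
            "C.A.3" = 50, "C.D.3.1" = 80)
  expect_equal(timed$nodes$display_time[match(names(want), timed$nodes$code)],
               unname(want))
  expect_error(enhance(g, stats[stats$code != "C.O.2.1", ]), "C\\.O\\.2\\.1")
})

test_that("offsets, stats and labels are invariant under time translation", {
  log <- fixed_offset_cohort(n = 8)
  shifted <- log
  year <- 365 * 86400
  shifted$events$timestamp <- shifted$events$timestamp + year
  for (col in c("onset_time", "arrival_time", "neurology_arrival_time")) {
    shifted$patients[[col]] <- shifted$patients[[col]] + year
  }
  s1 <- compute_stats(log)
  s2 <- compute_stats(shifted)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  t1 <- enhance(discover(log, 0, 0), s1)
  t2 <- enhance(discover(shifted, 0, 0), s2)
  expect_equal(t1$nodes$label, t2$nodes$label)
})
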