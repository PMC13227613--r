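mk_event <- function(style, report = "2026-01-05 10:00:00", labels = "Standing",
                     start = NA, end = NA, dur = NA, pid = "P1", idx = 1L) {
  data.table::data.table(
    participant_id = pid,
    report_time = as.POSIXct(report, tz = "UTC"),
    event_index = idx, labels = labels, event_class = NA_character_,
    cue_style = style,
    stated_start = as.POSIXct(start, tz = "UTC"),
    stated_end = as.POSIXct(end, tz = "UTC"),
    stated_duration_min = as.numeric(dur), raw_text = "")
}

utc <- function(x) as.POSIXct(x, tz = "UTC")

test_that("interval reconstruction follows each cue style", {
  ev <- rbind(
    mk_event("C1", report = "2026-01-05 10:00:00", dur = 20),
    mk_event("C4", start = "2026-01-05 17:00:00", end = "2026-01-05 19:00:00"),
    mk_event("C7", report = "2026-01-05 14:05:00", dur = 20),
    mk_event("C3", report = "2026-01-05 12:00:00"),
    mk_event("C6", report = "2026-01-05 11:00:00", start = "2026-01-05 10:40:00"),
    mk_event("I2"))
  out <- reconstruct_intervals(validate_verbal_events(ev))
  out <- out[order(cue_style)]
  expect_equal(out[cue_style == "C1", interval_start], utc("2026-01-05 09:40:00"))
  expect_equal(out[cue_style == "C1", interval_end], utc("2026-01-05 10:00:00"))
  expect_equal(out[cue_style == "C4", interval_start], utc("2026-01-05 17:00:00"))
  expect_equal(out[cue_style == "C4", interval_end], utc("2026-01-05 19:00:00"))
  expect_equal(out[cue_style == "C7", interval_start], utc("2026-01-05 14:05:00"))
  expect_equal(out[cue_style == "C7", interval_end], utc("2026-01-05 14:25:00"))
  expect_equal(out[cue_style == "C3", interval_end] -
                 out[cue_style == "C3", interval_start],
               as.difftime(1, units = "mins"))
  expect_equal(out[cue_style == "C6", interval_start], utc("2026-01-05 10:40:00"))
  expect_true(is.na(out[cue_style == "I2", interval_start]))
})

test_that("C2 uses the previous report; orphans and degenerates fall back", {
  ev <- rbind(mk_event("C3", report = "2026-01-05 09:00:00"),
              mk_event("C2", report = "2026-01-05 10:00:00"))
  out <- reconstruct_intervals(validate_verbal_events(ev))
  expect_equal(out[cue_style == "C2", interval_start], utc("2026-01-05 09:00:00"))

  orphan <- mk_event("C2", report = "2026-01-05 08:00:00")
  expect_warning(out <- reconstruct_intervals(validate_verbal_events(orphan)),
                 "preceding")
  expect_true(is.na(out$interval_start))

  bad <- mk_event("C6", report = "2026-01-05 10:00:00",
                  start = "2026-01-05 11:00:00")
  expect_warning(out <- reconstruct_intervals(validate_verbal_events(bad)),
                 "end <= start")
  expect_true(is.na(out$interval_start))
})

test_that("C1 and C7 conserve the stated duration", {
  for (dur in c(1, 7, 45, 120)) {
    ev <- rbind(mk_event("C1", dur = dur), mk_event("C7", dur = dur, idx = 1L,
                                                    report = "2026-01-05 11:00:00"))
    out <- reconstruct_intervals(validate_verbal_events(ev))
    lens <- as.numeric(out$interval_end) - as.numeric(out$interval_start)
    expect_equal(lens, rep(dur * 60, 2))
  }
})

test_that("event_class derives from the label set and C4 needs both times", {
  ev <- rbind(mk_event("C3", labels = "Standing"),
              mk_event("C3", labels = "Standing|LowStepping"),
              mk_event("C3", labels = ""))
  out <- validate_verbal_events(ev)
  expect_equal(out$event_class, c("singleton", "composite", "undefined"))
  expect_error(validate_verbal_events(mk_event("C4", start = "2026-01-05 10:00:00")),
               "C4")
  expect_error(validate_verbal_events(mk_event("C9")), "cue style")
  expect_error(validate_verbal_events(mk_event("C3", labels = "Jogging")),
               "unknown activity")
})

test_that("expansion tally satisfies the entry/event identity", {
  b <- small_bundle()
  tally <- expand_entries(b$verbal$events)
  expect_true(tally$identity_holds)
  gen <- b$verbal$tally
  expect_equal(tally$entries_total, sum(gen$entries))
  expect_equal(tally$events_total, sum(gen$events))
  # single-event entries pass through unchanged
  one <- mk_event("C3")
  t1 <- expand_entries(one)
  expect_equal(t1$entries_expanded, 0)
  expect_equal(t1$events_total, 1)
})

test_that("exclusions are mutually exclusive and account for every event", {
  wear <- data.table::data.table(
    participant_id = "P1",
    minute_start = utc("2026-01-05 10:00:00") + 60 * (0:59),
    worn = rep(c(TRUE, FALSE), each = 30))
  ev <- rbind(
    mk_event("C1", report = "2026-01-05 10:20:00", dur = 10),  # worn, kept
    mk_event("C1", report = "2026-01-05 10:50:00", dur = 10,
             labels = ""),                                     # undefined
    mk_event("I1"),                                            # no time
    mk_event("I3", labels = ""),                               # both
    mk_event("C1", report = "2026-01-05 10:50:00", dur = 10),  # unworn period
    mk_event("C1", report = "2026-01-05 10:35:00", dur = 10))  # straddles
  out <- apply_exclusions(reconstruct_intervals(validate_verbal_events(ev)),
                          wear)
  cnt <- out$tally$counts
  expect_equal(unname(cnt[c("retained", "no_time", "no_label", "both",
                            "not_worn", "truncated")]),
               c(2, 1, 1, 1, 1, 1))
  expect_equal(cnt[["events_total"]],
               cnt[["retained"]] + cnt[["no_time"]] + cnt[["no_label"]] +
                 cnt[["both"]] + cnt[["not_worn"]])
})

test_that("injected defect rates are recovered in the exclusion tally", {
  b <- default_bundle()
  cfg <- cohort_config(seed = 42)
  ev <- suppressWarnings(reconstruct_intervals(b$verbal$events))
  out <- apply_exclusions(ev, wear_mask = NULL)
  cnt <- out$tally$counts
  n <- cnt[["events_total"]]
  p_i <- sum(cfg$style_probs[c("I1", "I2", "I3")])
  p_both <- p_i * cfg$undefined_given_I
  p_no_label <- (1 - p_i) * cfg$undefined_given_C
  # no_time also absorbs C2 orphans and degenerate reconstructions, so
  # compare it one-sided and the label channels two-sided
  expect_true(within_multinomial_ci(
    c(cnt[["no_label"]], n - cnt[["no_label"]]),
    c(p_no_label, 1 - p_no_label)))
  expect_true(within_multinomial_ci(
    c(cnt[["both"]], n - cnt[["both"]]), c(p_both, 1 - p_both)))
  expect_gte(cnt[["no_time"]] / n, (p_i - p_both) - 0.03)
})

test_that("projection applies the 30 s coverage rule and unions labels", {
  ev <- mk_event("C4", start = "2026-01-05 10:00:00",
                 end = "2026-01-05 10:30:00", labels = "Standing|LowStepping")
  out <- project_to_minutes(reconstruct_intervals(validate_verbal_events(ev)))
  expect_equal(nrow(out), 30)
  expect_true(all(out$labels == "LowStepping|Standing"))

  ev2 <- mk_event("C4", start = "2026-01-05 10:00:40",
                  end = "2026-01-05 10:02:00")
  out2 <- project_to_minutes(reconstruct_intervals(validate_verbal_events(ev2)))
  expect_equal(format(out2$minute_start, "%H:%M"), "10:01")  # 20 s overlap dropped

  ev3 <- rbind(
    mk_event("C4", start = "2026-01-05 10:00:00", end = "2026-01-05 10:10:00",
             labels = "Standing"),
    mk_event("C4", start = "2026-01-05 10:05:00", end = "2026-01-05 10:15:00",
             labels = "LowStepping"))
  out3 <- project_to_minutes(reconstruct_intervals(validate_verbal_events(ev3)))
  shared <- out3[format(minute_start, "%H:%M") %in%
                   sprintf("10:%02d", 5:9), labels]
  expect_true(all(shared == "LowStepping|Standing"))
  # projected minutes never leave the interval
  expect_true(all(out3$minute_start >= utc("2026-01-05 10:00:00") &
                    out3$minute_start < utc("2026-01-05 10:15:00")))
})

test_that("verbal CSV and JSON-lines round-trip", {
  ev <- rbind(mk_event("C1", dur = 20), mk_event("C4",
                                                 start = "2026-01-05 17:00:00",
                                                 end = "2026-01-05 19:00:00"))
  f <- tempfile(fileext = ".csv")
  tmp <- data.table::copy(ev)
  tmp[, report_time := format(report_time, "%Y-%m-%dT%H:%M:%S")]
  tmp[, stated_start := ifelse(is.na(stated_start), "",
                               format(stated_start, "%Y-%m-%dT%H:%M:%S"))]
  tmp[, stated_end := ifelse(is.na(stated_end), "",
                             format(stated_end, "%Y-%m-%dT%H:%M:%S"))]
  data.table::fwrite(tmp, f)
  back <- read_verbal_events(f)
  expect_equal(back$cue_style, ev$cue_style)
  expect_equal(as.numeric(back$report_time), as.numeric(ev$report_time))
  fj <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(tmp)), function(k)
    jsonlite::toJSON(as.list(tmp[k]), auto_unbox = TRUE, na = "null"),
    character(1)), fj)
  backj <- read_verbal_events(fj)
  expect_equal(backj$cue_style, ev$cue_style)
  unlink(c(f, fj))
})
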