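mk_epoch <- function(sedentary = 0, sitt = 0, lp = 0, ls = 0, upright = 0,
                     step = 0, cyc = 0, steps = 0, pid = "P1") {
  data.table::data.table(participant_id = pid,
                         minute_start = as.POSIXct("2026-01-05 10:00:00", tz = "UTC"),
                         sedentary_s = sedentary, sitting_transport_s = sitt,
                         lying_primary_s = lp, lying_secondary_s = ls,
                         upright_s = upright, stepping_s = step, cycling_s = cyc,
                         steps = steps, met = NA_real_)
}

test_that("derive_durations applies the aggregation and subtraction rules", {
  d <- derive_durations(mk_epoch(sedentary = 60, sitt = 60))
  expect_equal(d$sitting_not_transport_s, 0)
  d <- derive_durations(mk_epoch(lp = 20, ls = 25))
  expect_equal(d$lying_s, 45)
  d <- derive_durations(mk_epoch(upright = 60, step = 20, cyc = 10))
  expect_equal(d$standing_s, 30)
})

test_that("negative remainders are clamped within tolerance, flagged beyond", {
  expect_warning(d <- derive_durations(mk_epoch(sedentary = 59.5, sitt = 60)),
                 "clamped")
  expect_equal(d$sitting_not_transport_s, 0)
  expect_false(d$invalid)
  d <- suppressWarnings(derive_durations(mk_epoch(upright = 30, step = 25, cyc = 10)))
  expect_true(d$invalid)
  lab <- assign_epoch_label(d)
  expect_equal(lab$label, excluded_label())
})

test_that("the >30 s rule is strict and exhaustive", {
  lab <- assign_epoch_label(mk_epoch(sedentary = 29, upright = 31))
  expect_equal(lab$label, "Standing")
  expect_equal(lab$basis_seconds, 31)
  lab <- assign_epoch_label(mk_epoch(sedentary = 30, upright = 30))
  expect_equal(lab$label, excluded_label())
})

test_that("stepping wins are refined by personalized thresholds", {
  th <- data.table::data.table(participant_id = c("P13", "P1"),
                               theta_LM = c(90, 80), theta_MV = c(130, NA))
  lab <- assign_epoch_label(mk_epoch(upright = 60, step = 60, steps = 96,
                                     pid = "P13"), th)
  expect_equal(lab$label, "ModerateStepping")
  lab <- assign_epoch_label(mk_epoch(upright = 60, step = 60, steps = 85,
                                     pid = "P1"), th)
  expect_equal(lab$label, "ModerateStepping")   # no theta_MV: >= theta_LM caps at Moderate
  lab <- assign_epoch_label(mk_epoch(upright = 60, step = 60, steps = 135,
                                     pid = "P13"), th)
  expect_equal(lab$label, "VigorousStepping")
  expect_error(assign_epoch_label(mk_epoch(upright = 60, step = 60, steps = 50)),
               "thresholds")
})

test_that("cadence boundary is inclusive on the higher-intensity side", {
  expect_equal(classify_stepping_intensity(90, 90, 130), "ModerateStepping")
  expect_equal(classify_stepping_intensity(89.9, 90, 130), "LowStepping")
  expect_equal(classify_stepping_intensity(130, 90, 130), "VigorousStepping")
  expect_error(classify_stepping_intensity(-1, 90), "negative")
})

test_that("threshold monotonicity: raising theta_LM never promotes a minute", {
  steps <- seq(40, 170, by = 1)
  rank_of <- c(LowStepping = 1, ModerateStepping = 2, VigorousStepping = 3)
  for (lm in c(80, 90, 100)) {
    a <- rank_of[classify_stepping_intensity(steps, lm, 130)]
    b <- rank_of[classify_stepping_intensity(steps, lm + 10, 130)]
    expect_true(all(b <= a))
  }
})

test_that("assign_epoch_label matches the brute-force oracle on random compositions", {
  epochs <- random_epochs(2000, seed = 11)
  th <- data.table::data.table(participant_id = "PX", theta_LM = 90,
                               theta_MV = 130)
  got <- suppressWarnings(assign_epoch_label(derive_durations(epochs), th))
  want <- vapply(seq_len(nrow(epochs)),
                 function(k) epoch_oracle(as.list(epochs[k])), character(1))
  expect_identical(got$label, want)
})

test_that("at most one derived duration can strictly exceed 30 s", {
  epochs <- derive_durations(random_epochs(2000, seed = 12))
  mat <- as.matrix(epochs[, .(lying_s, sitting_not_transport_s,
                              sitting_transport_s, standing_s, stepping_s,
                              cycling_s)])
  expect_true(all(rowSums(mat > 30) <= 1))
  # conservation: derived durations resum to the source composition
  resum <- epochs$lying_s + epochs$sitting_not_transport_s +
    epochs$sitting_transport_s + epochs$standing_s + epochs$stepping_s +
    epochs$cycling_s
  src <- epochs$sedentary_s + epochs$lying_primary_s +
    epochs$lying_secondary_s + epochs$upright_s
  expect_true(all(abs(resum - src) <= 1))
})

test_that("exclusion_rate counts sentinels only", {
  expect_equal(exclusion_rate(c("Standing", "Lying")), 0)
  expect_equal(exclusion_rate(c(excluded_label(), "Lying")), 0.5)
  expect_error(exclusion_rate(character(0)), "empty")
})

test_that("epoch CSV round-trips through the readers", {
  epochs <- random_epochs(50, seed = 13)
  f <- tempfile(fileext = ".csv")
  tmp <- data.table::copy(epochs)[, minute_start := format(minute_start,
                                                           "%Y-%m-%dT%H:%M:%S")]
  data.table::fwrite(tmp, f)
  back <- read_thigh_epochs(f)
  expect_equal(back$sedentary_s, epochs$sedentary_s)
  expect_equal(as.numeric(back$minute_start), as.numeric(epochs$minute_start))
  th <- data.table::data.table(participant_id = "PX", theta_LM = 90, theta_MV = 130)
  lab <- suppressWarnings(assign_epoch_label(derive_durations(back), th))
  f2 <- tempfile(fileext = ".csv")
  write_epoch_labels(lab, f2)
  expect_true(file.exists(f2))
  unlink(c(f, f2))
})
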