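test_that("ROC endpoints, monotonicity, and degenerate shapes", {
  roc <- roc_points(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))   # perfect separation
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))

  flat <- roc_points(rep(50, 10), rep(c(0, 1), 5))
  expect_equal(nrow(flat), 2)                      # diagonal: (0,0) -> (1,1)
  expect_error(roc_points(1:4, rep(1, 4)), "single-class")
})

test_that("Youden maximization matches the tie-break convention", {
  y <- youden_optimal(roc_points(c(90, 80, 30, 20), c(1, 1, 0, 0)))
  expect_equal(y$J, 1)
  expect_equal(y$threshold, 80)
  y0 <- youden_optimal(roc_points(rep(10, 6), c(1, 0, 1, 0, 1, 0)))
  expect_equal(y0$J, 0)
  expect_equal(y0$threshold, Inf)   # ties break toward the highest threshold
})

test_that("AUC hits the trivial anchors and the pairwise oracle", {
  expect_equal(auc_score(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  set.seed(7)
  for (k in 1:25) {
    n <- sample(10:60, 1)
    conf <- sample(0:100, n, replace = TRUE)      # heavy ties
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) == 0 || sum(truth) == n) next
    expect_equal(auc_score(conf, truth), auc_oracle(conf, truth),
                 tolerance = 1e-12)
    y <- youden_optimal(roc_points(conf, truth))
    yo <- youden_oracle(conf, truth)
    expect_equal(y$J, yo$J, tolerance = 1e-12)
    expect_equal(y$threshold, yo$threshold)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(8)
  conf <- runif(200); truth <- rbinom(200, 1, 0.5)
  a <- auc_score(conf, truth)
  expect_equal(auc_score(conf^3, truth), a, tolerance = 1e-12)
  expect_equal(auc_score(exp(5 * conf), truth), a, tolerance = 1e-12)
  expect_equal(auc_score(rank(conf), truth), a, tolerance = 1e-12)
})

mk_frames <- function(n = 50, pid = "P1") {
  minutes <- as.POSIXct("2026-01-05 10:00:00", tz = "UTC") + 60 * seq_len(n)
  lab <- rep_len(c("VigorousStepping", "SittingInTransport", "Standing",
                   "Cycling", "LowStepping"), n)
  dt <- data.table::data.table(participant_id = pid, minute_start = minutes,
                               worn = TRUE, thigh_label = lab,
                               verbal_labels = lab, consensus_label = lab)
  for (col in c("still", "in_vehicle", "on_foot", "walking", "running",
                "on_bicycle", "tilting", "unknown")) dt[, (col) := 10]
  dt
}

test_that("binarize_truth maps labels through the class sets", {
  fr <- mk_frames()
  b <- binarize_truth(fr, "RUNNING", "consensus")
  expect_equal(b$truth, as.integer(fr$consensus_label == "VigorousStepping"))
  b2 <- binarize_truth(fr, "STILL", "consensus")
  expect_true(all(b2$truth[fr$consensus_label == "SittingInTransport"] == 0))
  expect_true(all(b2$truth[fr$consensus_label == "Standing"] == 1))
  fr$verbal_labels <- "LowStepping|Standing"
  b3 <- binarize_truth(fr, "WALKING", "verbal")
  expect_true(all(b3$truth == 1))
  expect_error(binarize_truth(fr, "TILTING", "consensus"), "not evaluable")
})

test_that("compare_sources handles clean, shuffled and single-class cells", {
  b <- cached("zero_bundle", simulate_cohort(small_cfg(seed = 5, noise = "none")))
  res <- quiet_pipeline(b, api = b$api$confidences)
  ok <- res$auc[evaluable == TRUE]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$auc > 0.999))
  # shuffled confidences are uninformative
  fr <- data.table::copy(res$frames)
  set.seed(9)
  for (col in c("running", "on_bicycle")) fr[, (col) := sample(fr[[col]])]
  shuf <- compare_sources(fr, classes = c("RUNNING", "ON_BICYCLE"),
                          sources = "consensus")
  for (k in seq_len(nrow(shuf))) {
    if (!shuf$evaluable[k]) next
    se <- sqrt(0.25 / min(shuf$n_pos[k], shuf$n_neg[k]))
    expect_lt(abs(shuf$auc[k] - 0.5), 5 * se)
  }
  # single-class cells are marked, not fatal
  fr2 <- mk_frames()
  fr2[, consensus_label := "Standing"]
  fr2[, verbal_labels := "Standing"]; fr2[, thigh_label := "Standing"]
  out <- compare_sources(fr2, classes = "RUNNING")
  expect_true(all(!out$evaluable))
  expect_true(all(is.na(out$auc)))
})

test_that("error crosstab conserves evaluated minutes and tracks injections", {
  fr <- mk_frames(400)
  set.seed(10)
  fr[, in_vehicle := ifelse(consensus_label == "SittingInTransport",
                            runif(.N, 60, 100), runif(.N, 0, 40))]
  fr[, still := ifelse(consensus_label %in% api_label_set("STILL"),
                       runif(.N, 60, 100), runif(.N, 0, 40))]
  tab <- error_crosstab(fr)
  n_eval <- nrow(fr)
  expect_equal(sum(tab$IN_VEHICLE_detected) + sum(tab$IN_VEHICLE_not_detected),
               n_eval)
  expect_equal(sum(tab$STILL_detected) + sum(tab$STILL_not_detected), n_eval)
  # inject motorized-tool minutes: Standing with vehicle-like confidence
  stand <- which(fr$consensus_label == "Standing")
  fp_before <- tab[consensus_label == "Standing", IN_VEHICLE_detected]
  fr2 <- data.table::copy(fr)
  fr2[stand[1:40], in_vehicle := 95]
  tab2 <- error_crosstab(fr2, thresholds = c(IN_VEHICLE = 50, STILL = 50))
  expect_gte(tab2[consensus_label == "Standing", IN_VEHICLE_detected],
             fp_before + 40 - 5)
  # empty cohort: all-zero table
  tab0 <- error_crosstab(fr[0], thresholds = c(IN_VEHICLE = 50, STILL = 50))
  expect_true(all(tab0[, -1] == 0))
})

test_that("higher motorized-tool rates monotonically grow the FP cell", {
  cfg0 <- small_cfg(seed = 3)
  truth <- simulate_truth(cfg0)
  wear <- wear_mask_from_truth(truth)
  fp_counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(r) {
    cfg <- small_cfg(seed = 3, api_noise = list(motorized_tool_invehicle = r))
    api <- observe_api(truth, wear, cfg)
    m <- merge(truth$minutes, api$confidences,
               by = c("participant_id", "minute_start"))
    sum(m$label == "Standing" & m$in_vehicle >= 50)
  }, numeric(1))
  expect_true(all(diff(fp_counts) > 0))
})
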