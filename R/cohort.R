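# Synthetic multi-source cohort generator. Emulates the structure of the
# original deployment -- 13 older adults, 7 days, a thigh sensor worn
# ~24/7, a smartwatch worn ~10.3 h/day, hourly-ish verbal reports -- with
# every error channel the pipeline must tolerate made explicit and
# configurable: minute fragmentation (alternating activities), posture
# confusion, intensity-dependent under-reporting, the empirical
# time-cue-style mix, recall noise, and recognizer error modes.

COHORT_CLASSES <- c("Lying", "SittingNotInTransport", "SittingInTransport",
                    "Standing", "LowStepping", "ModerateStepping",
                    "VigorousStepping", "Cycling")

# empirical time-cue style mix (event counts out of 1,357)
STYLE_COUNTS <- c(C1 = 440, C2 = 297, C3 = 259, C4 = 87, C5 = 69, C6 = 59,
                  C7 = 47, I1 = 52, I2 = 33, I3 = 14)

# classes whose minutes fragment into alternating activities, and their
# companion classes for two- and three-way splits
FRAG_COMPANION <- c(SittingNotInTransport = "Standing",
                    Standing = "LowStepping",
                    LowStepping = "Standing")
FRAG_THIRD <- c(SittingNotInTransport = "LowStepping",
                Standing = "SittingNotInTransport",
                LowStepping = "SittingNotInTransport")

#' Cohort generator configuration
#'
#' Defaults state the simulated world once: sample sizes mirror the
#' original deployment (13 participants, 7 days), the smartwatch is worn
#' about 10.3 h/day, verbal time-cue styles follow the empirical mix,
#' verbal coverage is intensity-dependent (high-intensity activities are
#' reported far more reliably), and the recognizer exhibits the documented
#' error modes (motorized tools mimicking vehicles, idling vehicles
#' missed, still wrists while cycling).
#'
#' @param n_participants,n_days Cohort dimensions (defaults 13 and 7).
#' @param seed Integer master seed; per-participant substreams are derived
#'   from it so adding participants never perturbs existing ones.
#' @param noise `"default"` for the realistic world, `"none"` for the
#'   noise-free identity world (full coverage, all-C4 styles, no
#'   fragmentation/confusion/recall noise, deterministic recognizer).
#' @param ... Named overrides of any default component (see the returned
#'   list for names).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 13, n_days = 7, seed = 1,
                          noise = c("default", "none"), ...) {
  noise <- match.arg(noise)
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    seed = as.integer(seed),
    origin = "2026-01-05",
    # semi-Markov daytime structure
    dwell_mean = c(Lying = 45, SittingNotInTransport = 40,
                   SittingInTransport = 18, Standing = 8, LowStepping = 6,
                   ModerateStepping = 18, VigorousStepping = 15, Cycling = 25),
    dwell_shape = 2,
    transition_weights = c(Lying = 0.03, SittingNotInTransport = 0.32,
                           SittingInTransport = 0.05, Standing = 0.30,
                           LowStepping = 0.20, ModerateStepping = 0.06,
                           VigorousStepping = 0.04, Cycling = 0.02),
    vigorous_participants = c(5, 13),
    wake_mean_min = 405, wake_sd_min = 30,     # ~6:45
    bed_mean_min = 1350, bed_sd_min = 30,      # ~22:30
    # wear schedule
    worn_delay_mean = 20, worn_delay_sd = 10,
    worn_duration_mean = 620, worn_duration_sd = 45,  # ~10.3 h
    thigh_removal_prob = 6 / 91,               # removal episodes per day
    thigh_removal_duration = c(mean = 60, sd = 15),
    # thigh observation channels
    frag_two_prob = 0.30, frag_three_prob = 0.075,
    posture_confusion = c(stool_sit_standing = 0.06, lying_as_sitting = 0.10,
                          sitting_as_lying = 0.02, cycling_as_upright = 0.12,
                          stepping_as_cycling = 0.015),
    # per-participant cadence mixtures: valleys anchored to the published
    # per-participant thresholds; components sit +/- `delta` around them
    cadence_delta = 18, cadence_sd = 8, cadence_vig_offset = 15,
    # verbal reporting
    report_coverage = c(Lying = 0.25, SittingNotInTransport = 0.40,
                        SittingInTransport = 0.55, Standing = 0.30,
                        LowStepping = 0.35, ModerateStepping = 0.80,
                        VigorousStepping = 0.95, Cycling = 0.92),
    style_probs = STYLE_COUNTS / sum(STYLE_COUNTS),
    undefined_given_C = 62 / 1258,
    undefined_given_I = 17 / 99,
    recall_noise_sd = 5,
    composite_prob = 0.30,
    series_prob = 0.08,
    # recognizer noise
    api_noise = list(tp_shape = c(10, 2.5), bg_shape = c(1.5, 12),
                     motorized_tool_invehicle = 0.05,
                     idle_vehicle_miss = 0.30,
                     cycling_wrist_still = 0.15)
  )
  if (noise == "none") {
    cfg$frag_two_prob <- 0
    cfg$frag_three_prob <- 0
    cfg$posture_confusion[] <- 0
    cfg$thigh_removal_prob <- 0
    cfg$worn_delay_mean <- 0; cfg$worn_delay_sd <- 0
    cfg$worn_duration_mean <- Inf; cfg$worn_duration_sd <- 0
    cfg$report_coverage[] <- 1
    cfg$style_probs <- c(C1 = 0, C2 = 0, C3 = 0, C4 = 1, C5 = 0, C6 = 0,
                         C7 = 0, I1 = 0, I2 = 0, I3 = 0)
    cfg$undefined_given_C <- 0
    cfg$undefined_given_I <- 0
    cfg$recall_noise_sd <- 0
    cfg$composite_prob <- 0
    cfg$series_prob <- 0
    cfg$cadence_sd <- 0.5
    cfg$api_noise$motorized_tool_invehicle <- 0
    cfg$api_noise$idle_vehicle_miss <- 0
    cfg$api_noise$cycling_wrist_still <- 0
    cfg$api_noise$tp_shape <- c(1e4, 1)   # essentially deterministic
    cfg$api_noise$bg_shape <- c(1, 1e4)
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else if (!is.null(names(cfg[[nm]])) && !is.null(names(over[[nm]])) &&
               length(over[[nm]]) < length(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1, cfg$n_days >= 1)
  if (abs(sum(cfg$style_probs) - 1) > 1e-6) stop("style_probs must sum to 1")
  probs <- c(cfg$report_coverage, cfg$frag_two_prob, cfg$frag_three_prob,
             cfg$posture_confusion, cfg$composite_prob, cfg$series_prob,
             cfg$undefined_given_C, cfg$undefined_given_I)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$dwell_mean <= 0)) stop("dwell means must be positive")
  if (cfg$frag_two_prob + cfg$frag_three_prob > 1)
    stop("fragmentation probabilities must sum to at most 1")
  structure(cfg, class = "cohort_config")
}

participant_ids <- function(cfg) paste0("P", seq_len(cfg$n_participants))

# published per-participant low->moderate thresholds; recycled for larger
# synthetic cohorts
DEFAULT_THETA_LM <- c(80, 100, 80, 90, 100, 80, 80, 80, 90, 90, 90, 85, 90)
DEFAULT_THETA_MV <- c(NA, NA, NA, NA, 135, NA, NA, NA, NA, NA, NA, NA, 130)

#' Generating cadence mixture for one participant
#'
#' The low and moderate cadence components sit `delta` steps/min below and
#' above the participant's generating valley `theta_LM`; when the
#' participant has vigorous stepping, a third component sits above
#' `theta_MV`. These valleys are the oracle that threshold estimation is
#' tested against.
#'
#' @param cfg A [cohort_config()].
#' @param i Participant index.
#' @return List with component `means`, common `sd`, and generating
#'   valleys `theta_LM` / `theta_MV` (`NA` when absent).
#' @export
cadence_components <- function(cfg, i) {
  k <- ((i - 1) %% length(DEFAULT_THETA_LM)) + 1
  lm <- DEFAULT_THETA_LM[k]
  mv <- DEFAULT_THETA_MV[k]
  if (!(i %in% cfg$vigorous_participants)) mv <- NA_real_
  if (i %in% cfg$vigorous_participants && is.na(mv)) mv <- 132
  means <- c(Low = lm - cfg$cadence_delta, Moderate = lm + cfg$cadence_delta,
             Vigorous = if (is.na(mv)) NA_real_ else mv + cfg$cadence_vig_offset)
  list(means = means, sd = cfg$cadence_sd, theta_LM = lm, theta_MV = mv)
}

#' Simulate the true activity timeline
#'
#' Each participant-day has an overnight Lying block and a daytime
#' semi-Markov chain: next activity drawn from `transition_weights`
#' (self-transitions excluded; vigorous stepping restricted to
#' `vigorous_participants`), dwell gamma-distributed in whole minutes.
#' Deterministic under `(config, seed)`.
#'
#' @param cfg A [cohort_config()].
#' @return List with `minutes` (`participant_id`, `minute_start`, `label`,
#'   `episode_id`), `episodes` (`participant_id`, `episode_id`, `class`,
#'   `start`, `end`, `reportable`) and `days` (wake/bed/wear bounds).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  origin <- as.numeric(as.POSIXct(paste(cfg$origin, "00:00:00"), tz = "UTC"))
  all_eps <- vector("list", cfg$n_participants)
  all_days <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    pid <- paste0("P", i)
    w <- cfg$transition_weights
    if (!(i %in% cfg$vigorous_participants)) w["VigorousStepping"] <- 0
    if (all(w <= 0)) stop("transition weights must have positive mass")
    with_seed(substream_seed(cfg$seed, i, 1L), {
      eps <- list(); days <- list()
      for (d in seq_len(cfg$n_days)) {
        day0 <- origin + (d - 1) * 86400
        wake <- max(1, round(stats::rnorm(1, cfg$wake_mean_min, cfg$wake_sd_min)))
        bed <- min(1439, round(stats::rnorm(1, cfg$bed_mean_min, cfg$bed_sd_min)))
        if (bed <= wake + 60) { wake <- 405; bed <- 1350 }
        eps[[length(eps) + 1L]] <- data.table::data.table(
          class = "Lying", start = day0, end = day0 + wake * 60,
          reportable = FALSE)
        t <- wake
        prev <- "Lying"
        while (t < bed) {
          w2 <- w
          w2[prev] <- 0
          cls <- if (sum(w2) > 0) sample(COHORT_CLASSES, 1, prob = w2) else prev
          dwell <- max(1, round(stats::rgamma(1, shape = cfg$dwell_shape,
                                              scale = cfg$dwell_mean[cls] / cfg$dwell_shape)))
          e <- min(t + dwell, bed)
          eps[[length(eps) + 1L]] <- data.table::data.table(
            class = cls, start = day0 + t * 60, end = day0 + e * 60,
            reportable = TRUE)
          prev <- cls
          t <- e
        }
        eps[[length(eps) + 1L]] <- data.table::data.table(
          class = "Lying", start = day0 + bed * 60, end = day0 + 1440 * 60,
          reportable = FALSE)
        delay <- max(0, round(stats::rnorm(1, cfg$worn_delay_mean, cfg$worn_delay_sd)))
        dur <- round(stats::rnorm(1, min(cfg$worn_duration_mean, 1440),
                                  cfg$worn_duration_sd))
        worn_start <- min(wake + delay, bed)
        worn_end <- min(bed, worn_start + max(dur, 0))
        days[[length(days) + 1L]] <- data.table::data.table(
          day = d, wake = wake, bed = bed,
          worn_start = day0 + worn_start * 60, worn_end = day0 + worn_end * 60,
          day_start = day0)
      }
      ep <- data.table::rbindlist(eps)
      ep[, participant_id := pid]
      ep[, episode_id := seq_len(.N)]
      all_eps[[i]] <- ep
      dd <- data.table::rbindlist(days)
      dd[, participant_id := pid]
      all_days[[i]] <- dd
    })
  }
  episodes <- data.table::rbindlist(all_eps)
  days <- data.table::rbindlist(all_days)
  n_min <- (episodes$end - episodes$start) / 60
  minutes <- data.table::data.table(
    participant_id = rep(episodes$participant_id, n_min),
    minute_start = .POSIXct(unlist(mapply(function(s, e) seq(s, e - 60, by = 60),
                                          episodes$start, episodes$end,
                                          SIMPLIFY = FALSE)), tz = "UTC"),
    label = rep(episodes$class, n_min),
    episode_id = rep(episodes$episode_id, n_min))
  episodes[, start := .POSIXct(start, tz = "UTC")]
  episodes[, end := .POSIXct(end, tz = "UTC")]
  list(minutes = minutes[], episodes = episodes[], days = days[])
}

#' Smartwatch wear mask implied by the truth timeline
#'
#' @param truth Output of [simulate_truth()].
#' @return `data.table` with `participant_id`, `minute_start`, `worn`.
#' @export
wear_mask_from_truth <- function(truth) {
  out <- truth$minutes[, .(participant_id, minute_start)]
  out[, worn := FALSE]
  for (pid in unique(out$participant_id)) {
    idx <- which(out$participant_id == pid)
    key <- as.numeric(out$minute_start[idx])
    worn <- rep(FALSE, length(idx))
    dd <- truth$days[participant_id == pid]
    for (k in seq_len(nrow(dd))) {
      worn <- worn | (key >= as.numeric(dd$worn_start[k]) &
                        key < as.numeric(dd$worn_end[k]))
    }
    data.table::set(out, i = idx, j = "worn", value = worn)
  }
  out[]
}

#' Analytic epoch-exclusion probability of a generated world
#'
#' Fragmented minutes split their 60 seconds uniformly: a two-way split
#' has no >30 s majority only at the exact 30/30 cut (probability 1/59
#' over the 59 integer cut points); a three-way split has none when all
#' parts are <= 30 (493 of the 1711 integer compositions). The cohort
#' exclusion rate is therefore the fragmentable-minute share times the
#' mixture of those two atoms.
#'
#' @param truth Output of [simulate_truth()].
#' @param cfg The generating [cohort_config()].
#' @return Expected fraction of excluded thigh epochs.
#' @export
exclusion_probability <- function(truth, cfg) {
  lab <- truth$minutes$label
  pc <- cfg$posture_confusion
  share <- function(cl) mean(lab == cl)
  # probability a minute is *observed* as a fragmentable class, given the
  # posture-confusion channels applied before fragmentation
  frag_share <- share("SittingNotInTransport") * (1 - pc[["sitting_as_lying"]]) +
    share("Lying") * pc[["lying_as_sitting"]] +
    share("Standing") +
    share("LowStepping") * (1 - pc[["stepping_as_cycling"]]) +
    share("Cycling") * pc[["cycling_as_upright"]] * 2 / 3
  unname(frag_share * (cfg$frag_two_prob / 59 +
                       cfg$frag_three_prob * 493 / 1711))
}

#' Observe the truth through the thigh sensor
#'
#' Produces per-minute activity-second compositions. Error channels:
#' minutes of fragmentable classes split their seconds with a companion
#' class (two- or three-way, uniform integer cuts), and posture-confusion
#' channels rewrite the observed class at configured rates (stool-sitting
#' seen as Standing, lying seen as sitting, sitting seen as lying).
#' Stepping minutes draw cadence from the participant's mixture component
#' matching the true intensity. Thigh-removal periods drop their minutes
#' from the table entirely.
#'
#' @param truth Output of [simulate_truth()].
#' @param cfg A [cohort_config()].
#' @return `data.table` in the epoch-export schema of
#'   [read_thigh_epochs()].
#' @export
observe_thigh <- function(truth, cfg) {
  mins <- data.table::copy(truth$minutes)
  out_list <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    pid <- paste0("P", i)
    m <- mins[participant_id == pid]
    comp <- cadence_components(cfg, i)
    with_seed(substream_seed(cfg$seed, i, 2L), {
      n <- nrow(m)
      obs <- m$label
      pc <- cfg$posture_confusion
      sitn <- obs == "SittingNotInTransport"
      u <- stats::runif(n)
      obs[sitn & u < pc[["stool_sit_standing"]]] <- "Standing"
      obs[sitn & u >= pc[["stool_sit_standing"]] &
            u < pc[["stool_sit_standing"]] + pc[["sitting_as_lying"]]] <- "Lying"
      lyin <- m$label == "Lying"
      obs[lyin & stats::runif(n) < pc[["lying_as_sitting"]]] <- "SittingNotInTransport"
      # sensor-placement channel: pedaling breaks read as upright activity
      cyc <- m$label == "Cycling"
      u2 <- stats::runif(n)
      obs[cyc & u2 < pc[["cycling_as_upright"]] * 2 / 3] <- "Standing"
      obs[cyc & u2 >= pc[["cycling_as_upright"]] * 2 / 3 &
            u2 < pc[["cycling_as_upright"]]] <- "ModerateStepping"
      # and the reverse: leg cadence during stepping read as pedaling
      stp <- m$label %in% c("LowStepping", "ModerateStepping")
      obs[stp & stats::runif(n) < pc[["stepping_as_cycling"]]] <- "Cycling"

      fragable <- obs %in% names(FRAG_COMPANION)
      r <- stats::runif(n)
      f2 <- fragable & r < cfg$frag_two_prob
      f3 <- fragable & !f2 & r < cfg$frag_two_prob + cfg$frag_three_prob
      # seconds per class for each minute
      secs <- matrix(0, n, length(COHORT_CLASSES),
                     dimnames = list(NULL, COHORT_CLASSES))
      secs[cbind(seq_len(n), match(obs, COHORT_CLASSES))] <- 60
      if (any(f2)) {
        cut1 <- sample(1:59, sum(f2), replace = TRUE)
        idx <- which(f2)
        for (j in seq_along(idx)) {
          k <- idx[j]
          companion <- FRAG_COMPANION[[obs[k]]]
          secs[k, obs[k]] <- cut1[j]
          secs[k, companion] <- 60 - cut1[j]
        }
      }
      if (any(f3)) {
        idx <- which(f3)
        for (j in seq_along(idx)) {
          k <- idx[j]
          cuts <- sort(sample(1:59, 2))
          parts <- c(cuts[1], cuts[2] - cuts[1], 60 - cuts[2])
          companion <- FRAG_COMPANION[[obs[k]]]
          third <- FRAG_THIRD[[obs[k]]]
          secs[k, obs[k]] <- parts[1]
          secs[k, companion] <- secs[k, companion] + parts[2]
          secs[k, third] <- secs[k, third] + parts[3]
        }
      }
      # cadence draws for any minute with stepping seconds
      step_cols <- c("LowStepping", "ModerateStepping", "VigorousStepping")
      stepping_s <- rowSums(secs[, step_cols, drop = FALSE])
      steps <- numeric(n)
      has_step <- stepping_s > 0
      if (any(has_step)) {
        dom <- step_cols[max.col(secs[has_step, step_cols, drop = FALSE],
                                 ties.method = "first")]
        mu <- comp$means[c(LowStepping = "Low", ModerateStepping = "Moderate",
                           VigorousStepping = "Vigorous")[dom]]
        cad <- stats::rnorm(sum(has_step), mu, comp$sd)
        cad <- pmax(cad, 1)
        steps[has_step] <- round(cad * stepping_s[has_step] / 60)
      }
      sedentary <- secs[, "SittingNotInTransport"] + secs[, "SittingInTransport"]
      upright <- secs[, "Standing"] + stepping_s + secs[, "Cycling"]
      lying <- secs[, "Lying"]
      lp <- round(lying * 0.7)
      ep <- data.table::data.table(
        participant_id = pid, minute_start = m$minute_start,
        sedentary_s = sedentary,
        sitting_transport_s = secs[, "SittingInTransport"],
        lying_primary_s = lp, lying_secondary_s = lying - lp,
        upright_s = upright, stepping_s = stepping_s,
        cycling_s = secs[, "Cycling"], steps = steps,
        met = round(ifelse(steps > 0, 1.25 + 0.029 * steps, 1.3), 2))
      # thigh removal periods
      drop <- rep(FALSE, n)
      dd <- truth$days[participant_id == pid]
      for (d in seq_len(nrow(dd))) {
        if (stats::runif(1) < cfg$thigh_removal_prob) {
          len <- max(10, round(stats::rnorm(1, cfg$thigh_removal_duration[["mean"]],
                                            cfg$thigh_removal_duration[["sd"]])))
          st <- dd$day_start[d] + sample(0:(1440 - len), 1) * 60
          drop <- drop | (as.numeric(m$minute_start) >= as.numeric(st) &
                            as.numeric(m$minute_start) < as.numeric(st) + len * 60)
        }
      }
      out_list[[i]] <- ep[!drop]
    })
  }
  data.table::rbindlist(out_list)
}

#' Observe the truth through verbal reports
#'
#' Reportable (daytime) episodes are verbally reported with class-specific
#' coverage; each reported episode becomes an activity event with a
#' time-cue style drawn from the configured mix, recall noise on its cue
#' fields, and the configured defect channels: I-styles lack usable time
#' cues, undefined events lack labels, composite merging unions an episode
#' with its successor, and series entries bundle consecutive events into
#' one voice entry.
#'
#' @param truth Output of [simulate_truth()].
#' @param cfg A [cohort_config()].
#' @return List with `events` (schema of [read_verbal_events()]) and
#'   `tally` (generator-side bookkeeping: reported / merged / entry
#'   counts).
#' @export
observe_verbal <- function(truth, cfg) {
  out <- vector("list", cfg$n_participants)
  tallies <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    pid <- paste0("P", i)
    eps <- truth$episodes[participant_id == pid & reportable == TRUE]
    with_seed(substream_seed(cfg$seed, i, 3L), {
      cov <- cfg$report_coverage[eps$class]
      reported <- stats::runif(nrow(eps)) < cov
      ev <- eps[reported]
      n_merged <- 0L
      if (nrow(ev) >= 2L && cfg$composite_prob > 0) {
        # recall merging affects the short low-intensity activities;
        # high-intensity episodes are reported as their own events
        low_set <- c("Lying", "SittingNotInTransport", "Standing", "LowStepping")
        merge_flag <- stats::runif(nrow(ev) - 1L) < cfg$composite_prob &
          ev$class[-nrow(ev)] %in% low_set & ev$class[-1L] %in% low_set
        keep <- rep(TRUE, nrow(ev))
        labels_list <- as.list(ev$class)
        for (k in which(merge_flag)) {
          if (!keep[k]) next                      # already consumed
          labels_list[[k]] <- union(labels_list[[k]], ev$class[k + 1L])
          data.table::set(ev, i = k, j = "end", value = ev$end[k + 1L])
          keep[k + 1L] <- FALSE
          n_merged <- n_merged + 1L
        }
        labels_list <- labels_list[keep]
        ev <- ev[keep]
      } else {
        labels_list <- as.list(ev$class)
      }
      n_ev <- nrow(ev)
      if (n_ev == 0L) {
        out[[i]] <- NULL
        tallies[[i]] <- data.table::data.table(participant_id = pid,
                                               episodes = nrow(eps),
                                               reported = 0L, merged = 0L,
                                               entries = 0L, series_entries = 0L,
                                               events = 0L)
      } else {
      sty <- sample(names(cfg$style_probs), n_ev, replace = TRUE,
                    prob = cfg$style_probs)
      is_i <- substr(sty, 1, 1) == "I"
      undef <- stats::runif(n_ev) < ifelse(is_i, cfg$undefined_given_I,
                                           cfg$undefined_given_C)
      st <- as.numeric(ev$start); en <- as.numeric(ev$end)
      dur_min <- (en - st) / 60
      nz <- function(n) stats::rnorm(n, 0, cfg$recall_noise_sd)
      report <- en + 60 * sample(0:3, n_ev, replace = TRUE)
      stated_start <- rep(NA_real_, n_ev)
      stated_end <- rep(NA_real_, n_ev)
      stated_dur <- rep(NA_real_, n_ev)
      k <- sty == "C1"
      stated_dur[k] <- pmax(1, round(dur_min[k] + nz(sum(k))))
      report[k] <- en[k]
      k <- sty == "C2"; report[k] <- en[k]
      k <- sty == "C3"
      report[k] <- st[k] + 60 * floor(stats::runif(sum(k)) * pmax(dur_min[k], 1))
      k <- sty %in% c("C4", "C5")
      stated_start[k] <- round_to_minute(st[k] + 60 * nz(sum(k)))
      stated_end[k] <- round_to_minute(en[k] + 60 * nz(sum(k)))
      swap <- k & !is.na(stated_end) & stated_end <= stated_start
      stated_end[swap] <- stated_start[swap] + 60
      k <- sty == "C6"
      stated_start[k] <- round_to_minute(st[k] + 60 * nz(sum(k)))
      report[k] <- en[k]
      k <- sty == "C7"
      stated_dur[k] <- pmax(1, round(dur_min[k] + nz(sum(k))))
      report[k] <- st[k]
      # entry grouping: each event its own entry unless bundled in a series
      entry_key <- seq_len(n_ev)
      n_series <- 0L
      if (n_ev >= 2L && cfg$series_prob > 0) {
        bundle <- stats::runif(n_ev - 1L) < cfg$series_prob
        for (k2 in which(bundle)) {
          if (entry_key[k2] != k2) next
          entry_key[k2 + 1L] <- entry_key[k2]
          n_series <- n_series + 1L
        }
      }
      # events in one entry share the entry's report time (the recording);
      # distinct entries get distinct report minutes so entry identity
      # survives the CSV round-trip
      report <- round_to_minute(stats::ave(report, entry_key, FUN = max))
      seen <- numeric(0)
      for (ek in unique(entry_key)) {
        rows <- entry_key == ek
        t <- report[rows][1]
        while (t %in% seen) t <- t + 60
        seen <- c(seen, t)
        report[rows] <- t
      }
      labels_str <- vapply(labels_list, function(v) paste(sort(v), collapse = "|"),
                           character(1))
      labels_str[undef] <- ""
      raw <- verbal_phrase(labels_list, undef)
      dt <- data.table::data.table(
        participant_id = pid,
        report_time = .POSIXct(round_to_minute(report), tz = "UTC"),
        event_index = stats::ave(seq_len(n_ev), entry_key, FUN = seq_along),
        labels = labels_str,
        event_class = NA_character_,
        cue_style = sty,
        stated_start = .POSIXct(stated_start, tz = "UTC"),
        stated_end = .POSIXct(stated_end, tz = "UTC"),
        stated_duration_min = stated_dur,
        raw_text = raw,
        true_start = ev$start, true_end = ev$end)
      out[[i]] <- dt
      tallies[[i]] <- data.table::data.table(
        participant_id = pid, episodes = nrow(eps), reported = sum(reported),
        merged = n_merged, entries = length(unique(entry_key)),
        series_entries = n_series, events = n_ev)
      }
    })
  }
  events <- data.table::rbindlist(out)
  if (nrow(events)) events <- validate_verbal_events(events)
  list(events = events, tally = data.table::rbindlist(tallies))
}

round_to_minute <- function(x) round(x / 60) * 60

# short template phrases so exertion keywords exist for the audit
verbal_phrase <- function(labels_list, undef) {
  vapply(seq_along(labels_list), function(k) {
    if (undef[k]) return("did an hour of therapy")
    labs <- labels_list[[k]]
    if ("VigorousStepping" %in% labs) "went for a run, fairly intense"
    else if ("ModerateStepping" %in% labs) "walked at a moderate pace"
    else if ("LowStepping" %in% labs) "walking around the house"
    else if ("Cycling" %in% labs) "rode my bicycle"
    else if ("Lying" %in% labs) "lying on the couch"
    else if ("SittingInTransport" %in% labs) "driving to an appointment"
    else if ("Standing" %in% labs) "standing in the kitchen"
    else "sitting and reading"
  }, character(1))
}

#' Observe the truth through the recognizer
#'
#' For each smartwatch-worn minute, draws a confidence (0-100) per
#' recognizer class: a high (true-positive) beta draw for classes whose
#' mapped label set contains the true activity, a low (background) draw
#' otherwise. Error-mode overlays: motorized-tool minutes (true Standing)
#' boost `IN_VEHICLE`; idling-vehicle minutes (true seated transport)
#' suppress `IN_VEHICLE` and boost `STILL`; wrist-still cycling minutes
#' suppress `ON_BICYCLE` and boost `STILL`.
#'
#' @param truth Output of [simulate_truth()].
#' @param wear Wear mask from [wear_mask_from_truth()].
#' @param cfg A [cohort_config()].
#' @return List with `confidences` (schema of [read_api_confidences()])
#'   and `modes` (per-minute logical flags for the injected error modes).
#' @export
observe_api <- function(truth, wear, cfg) {
  out <- vector("list", cfg$n_participants)
  modes_out <- vector("list", cfg$n_participants)
  an <- cfg$api_noise
  for (i in seq_len(cfg$n_participants)) {
    pid <- paste0("P", i)
    m <- truth$minutes[participant_id == pid]
    w <- wear[participant_id == pid & worn == TRUE, minute_start]
    m <- m[minute_start %in% w]
    if (nrow(m) == 0L) next
    with_seed(substream_seed(cfg$seed, i, 4L), {
      n <- nrow(m)
      conf <- matrix(NA_real_, n, length(API_CONF_COLS),
                     dimnames = list(NULL, API_CONF_COLS))
      for (cls in api_classes()) {
        pos <- m$label %in% api_label_set(cls)
        draws <- numeric(n)
        draws[pos] <- 100 * stats::rbeta(sum(pos), an$tp_shape[1], an$tp_shape[2])
        draws[!pos] <- 100 * stats::rbeta(sum(!pos), an$bg_shape[1], an$bg_shape[2])
        conf[, conf_col(cls)] <- draws
      }
      tool <- m$label == "Standing" &
        stats::runif(n) < an$motorized_tool_invehicle
      idle <- m$label == "SittingInTransport" &
        stats::runif(n) < an$idle_vehicle_miss
      wrist <- m$label == "Cycling" & stats::runif(n) < an$cycling_wrist_still
      if (any(tool))
        conf[tool, "in_vehicle"] <- 100 * stats::rbeta(sum(tool), an$tp_shape[1],
                                                       an$tp_shape[2])
      if (any(idle)) {
        conf[idle, "in_vehicle"] <- 100 * stats::rbeta(sum(idle), an$bg_shape[1],
                                                       an$bg_shape[2])
        conf[idle, "still"] <- 100 * stats::rbeta(sum(idle), an$tp_shape[1],
                                                  an$tp_shape[2])
      }
      if (any(wrist)) {
        conf[wrist, "on_bicycle"] <- 100 * stats::rbeta(sum(wrist), an$bg_shape[1],
                                                        an$bg_shape[2])
        conf[wrist, "still"] <- 100 * stats::rbeta(sum(wrist), an$tp_shape[1],
                                                   an$tp_shape[2])
      }
      dt <- data.table::data.table(participant_id = pid,
                                   minute_start = m$minute_start)
      for (col in API_CONF_COLS) dt[, (col) := round(conf[, col], 2)]
      out[[i]] <- dt
      md <- data.table::data.table(participant_id = pid,
                                   minute_start = m$minute_start,
                                   motorized_tool = tool, idle_vehicle = idle,
                                   wrist_still = wrist)
      modes_out[[i]] <- md
    })
  }
  list(confidences = data.table::rbindlist(out),
       modes = data.table::rbindlist(modes_out))
}

#' Generate a complete multi-source cohort
#'
#' Runs [simulate_truth()], [wear_mask_from_truth()], [observe_thigh()],
#' [observe_verbal()] and [observe_api()] under one master seed and
#' returns the bundle plus provenance sufficient to regenerate it
#' bit-identically.
#'
#' @param cfg A [cohort_config()].
#' @return List of class `cohort_bundle`: `truth`, `wear_mask`,
#'   `thigh_epochs`, `verbal` (events + tally), `api` (confidences +
#'   modes), `provenance`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  truth <- simulate_truth(cfg)
  wear <- wear_mask_from_truth(truth)
  thigh <- observe_thigh(truth, cfg)
  verbal <- observe_verbal(truth, cfg)
  api <- observe_api(truth, wear, cfg)
  structure(list(truth = truth, wear_mask = wear, thigh_epochs = thigh,
                 verbal = verbal, api = api,
                 provenance = list(seed = cfg$seed,
                                   n_participants = cfg$n_participants,
                                   n_days = cfg$n_days,
                                   generator_version = "0.1.0",
                                   config = unclass(cfg))),
            class = "cohort_bundle")
}

#' Write a cohort bundle as the pipeline's input files
#'
#' Emits `thigh_epochs.csv`, `verbal_events.csv`, `wear_mask.csv`,
#' `api_confidences.csv`, `truth.csv` and `provenance.json` in the exact
#' schemas the ingestion functions read.
#'
#' @param bundle A [simulate_cohort()] bundle.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(thigh = file.path(dir, "thigh_epochs.csv"),
         verbal = file.path(dir, "verbal_events.csv"),
         wear = file.path(dir, "wear_mask.csv"),
         api = file.path(dir, "api_confidences.csv"),
         truth = file.path(dir, "truth.csv"),
         provenance = file.path(dir, "provenance.json"))
  th <- data.table::copy(bundle$thigh_epochs)
  th[, minute_start := format_minute(minute_start)]
  data.table::fwrite(th, p[["thigh"]])
  ev <- data.table::copy(bundle$verbal$events)
  if (nrow(ev)) {
    ev[, report_time := format_minute(report_time)]
    ev[, stated_start := ifelse(is.na(stated_start), "", format_minute(stated_start))]
    ev[, stated_end := ifelse(is.na(stated_end), "", format_minute(stated_end))]
    ev[, true_start := NULL]; ev[, true_end := NULL]
  }
  data.table::fwrite(ev, p[["verbal"]])
  wm <- data.table::copy(bundle$wear_mask)
  wm[, minute_start := format_minute(minute_start)]
  wm[, worn := as.integer(worn)]
  data.table::fwrite(wm, p[["wear"]])
  ap <- data.table::copy(bundle$api$confidences)
  ap[, minute_start := format_minute(minute_start)]
  data.table::fwrite(ap, p[["api"]])
  tr <- bundle$truth$minutes[, .(participant_id,
                                 minute_start = format_minute(minute_start),
                                 label)]
  data.table::fwrite(tr, p[["truth"]])
  jsonlite::write_json(bundle$provenance, p[["provenance"]], auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(p)
}
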