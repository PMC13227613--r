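# Summary tables from the original 13-participant deployment, shipped as
# plain-text fixtures. The raw study data are not public; these tables
# support exact recomputation of every printed ratio and accounting
# identity, which is how the reporting arithmetic of this package is
# validated.

#' Load a study summary fixture
#'
#' Available fixtures: `cadence_thresholds` (per-participant manual
#' stepping thresholds), `shrinkage_by_participant` (minute counts at each
#' labeling stage), `shrinkage_by_activity` (the same per activity),
#' `time_cue_styles` (event counts per time-cue style),
#' `event_accounting` (entry/event/exclusion counts).
#'
#' @param name Fixture name (without extension).
#' @return `data.table`.
#' @export
study_fixture <- function(name = c("cadence_thresholds",
                                   "shrinkage_by_participant",
                                   "shrinkage_by_activity",
                                   "time_cue_styles", "event_accounting")) {
  name <- match.arg(name)
  path <- system.file("extdata", "study", paste0(name, ".csv"),
                      package = "actconsensus", mustWork = TRUE)
  if (name == "cadence_thresholds") return(read_thresholds(path))
  data.table::fread(path)
}

#' Recompute the study's printed accounting quantities
#'
#' Every ratio and identity printed in the study's summary tables is
#' recomputed from the raw counts in the shipped fixtures, using the same
#' rounding the reports use (half-up to the printed precision). Nothing
#' here is hard-coded: change a fixture count and the output follows.
#'
#' @return Named list of recomputed quantities:
#' \describe{
#'   \item{consensus_over_imu_pct}{overall consensus retention of worn
#'     ("IMU") minutes, integer percent}
#'   \item{agreement_total_pct}{overall consensus share of verbally
#'     labeled minutes, integer percent}
#'   \item{agreement_by_participant_pct}{the same per participant (named)}
#'   \item{retention_by_activity_pct}{per-activity consensus share of
#'     thigh-labeled worn minutes, integer percent (named)}
#'   \item{consensus_over_thigh_imu_pct}{total consensus over
#'     thigh-labeled worn minutes, integer percent}
#'   \item{style_share_pct}{per-style event shares, percent to 1 decimal
#'     (named)}
#'   \item{incomplete_style_pct}{combined share of the I styles, 1 decimal}
#'   \item{events_total}{entry-expansion identity
#'     `entries - series + events_from_series`}
#'   \item{consensus_min_per_day}{consensus minutes per participant-day}
#'   \item{excluded_events_pct}{count-based share of excluded events, 1
#'     decimal}
#' }
#' @export
study_accounting <- function() {
  t5 <- study_fixture("shrinkage_by_participant")
  t6 <- study_fixture("shrinkage_by_activity")
  t7 <- study_fixture("time_cue_styles")
  ea <- study_fixture("event_accounting")
  cnt <- function(q) ea[quantity == q, count]

  agreement_p <- round_half_up(100 * t5$consensus_min / t5$verbal_min)
  names(agreement_p) <- t5$participant_id
  acts <- t6[activity != "CompositeOrUndefined"]
  retention_a <- round_half_up(100 * acts$consensus_min / acts$thigh_imu_min)
  names(retention_a) <- acts$activity

  events_total <- cnt("entries_total") - cnt("series_entries") +
    cnt("events_from_series")
  style_share <- round_half_up(100 * t7$count / sum(t7$count), 1)
  names(style_share) <- t7$style
  excluded_n <- cnt("excluded_no_time") + cnt("excluded_no_label") +
    cnt("excluded_both")

  list(
    consensus_over_imu_pct = round_half_up(100 * sum(t5$consensus_min) / sum(t5$imu_min)),
    agreement_total_pct = round_half_up(100 * sum(t5$consensus_min) / sum(t5$verbal_min)),
    agreement_by_participant_pct = agreement_p,
    retention_by_activity_pct = retention_a,
    consensus_over_thigh_imu_pct = round_half_up(
      100 * sum(t5$consensus_min) / sum(acts$thigh_imu_min)),
    style_share_pct = style_share,
    incomplete_style_pct = round_half_up(
      100 * sum(t7[style %in% c("I1", "I2", "I3"), count]) / sum(t7$count), 1),
    events_total = events_total,
    consensus_min_per_day = sum(t5$consensus_min) / (nrow(t5) * 7),
    excluded_events_pct = round_half_up(100 * excluded_n / events_total, 1)
  )
}
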