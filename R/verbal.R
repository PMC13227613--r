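# Verbal self-reports: structured annotations of voice entries are turned
# into per-minute label sets. Each activity event carries a label set
# (singleton / composite / undefined) and a time-cue style: C1..C7 admit
# interval reconstruction from combinations of report time, stated times
# and stated duration; I1..I3 are unreconstructable and excluded.

CUE_STYLES <- c(paste0("C", 1:7), paste0("I", 1:3))

VERBAL_COLS <- c("participant_id", "report_time", "event_index", "labels",
                 "event_class", "cue_style", "stated_start", "stated_end",
                 "stated_duration_min", "raw_text")

split_labels <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE),
         function(v) sort(unique(v[nzchar(v)])))
}

join_labels <- function(lst) {
  vapply(lst, function(v) paste(sort(unique(v)), collapse = "|"), character(1))
}

#' Read a structured verbal-event annotation file
#'
#' One record per activity event. Entries (voice recordings) are keyed by
#' `(participant_id, report_time)`; events within an entry are ordered by
#' `event_index`. `labels` is a pipe-separated set of leaf labels (empty
#' for undefined events); `raw_text` is opaque payload, carried but never
#' parsed.
#'
#' @param path CSV or JSON-lines file with the columns listed above.
#' @return `data.table` with timestamps parsed to POSIXct (UTC) and
#'   `event_class` derived from the label set when absent.
#' @export
read_verbal_events <- function(path) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    recs <- lapply(readLines(path, warn = FALSE), function(line) {
      l <- jsonlite::fromJSON(line)
      l[vapply(l, function(x) is.null(x) || length(x) == 0L, logical(1))] <- NA
      l
    })
    dt <- data.table::rbindlist(recs, fill = TRUE)
  } else {
    dt <- data.table::fread(path, colClasses = list(character = "labels"))
  }
  for (col in setdiff(VERBAL_COLS, names(dt))) {
    data.table::set(dt, j = col, value = if (col == "stated_duration_min")
      NA_real_ else NA_character_)
  }
  dt[, report_time := as_utc_time(report_time)]
  for (col in c("stated_start", "stated_end")) {
    v <- dt[[col]]
    v[!is.na(v) & !nzchar(as.character(v))] <- NA
    data.table::set(dt, j = col,
                    value = if (all(is.na(v))) .POSIXct(rep(NA_real_, nrow(dt)), tz = "UTC")
                            else as_utc_time(v))
  }
  dt[, stated_duration_min := as.numeric(stated_duration_min)]
  validate_verbal_events(dt)
}

#' Validate activity-event invariants
#'
#' Singleton events carry exactly one label, composite events two or more,
#' undefined events none; `event_class` is derived from the label set when
#' missing and cross-checked otherwise. Cue styles must be one of C1..C7,
#' I1..I3; C4 requires both stated times.
#'
#' @param events Event table (see [read_verbal_events()]).
#' @return The validated table (with `event_class` filled).
#' @export
validate_verbal_events <- function(events) {
  dt <- data.table::as.data.table(events)
  assert_cols(dt, setdiff(VERBAL_COLS, "raw_text"), "verbal events")
  bad_style <- setdiff(unique(dt$cue_style), CUE_STYLES)
  if (length(bad_style))
    stop("unknown cue styles: ", paste(bad_style, collapse = ", "))
  sets <- split_labels(dt$labels)
  known <- c(activity_labels())
  bad_lab <- setdiff(unlist(sets), known)
  if (length(bad_lab))
    stop("unknown activity labels: ", paste(bad_lab, collapse = ", "))
  n_lab <- lengths(sets)
  derived <- ifelse(n_lab == 0L, "undefined",
                    ifelse(n_lab == 1L, "singleton", "composite"))
  have <- !is.na(dt$event_class) & nzchar(dt$event_class)
  if (any(have & dt$event_class != derived))
    stop("event_class inconsistent with label set")
  dt[, event_class := derived]
  c4 <- dt$cue_style == "C4"
  if (any(c4 & (is.na(dt$stated_start) | is.na(dt$stated_end))))
    stop("C4 events require stated_start and stated_end")
  dt[]
}

#' Reconstruct activity intervals from time cues
#'
#' Applies the reconstruction rule of each time-cue style (durations in
#' minutes, intervals half-open):
#' \itemize{
#'   \item C1: `[report - duration, report)` -- "for the past N minutes"
#'   \item C2: `[previous report, report)` -- "since my last report"
#'   \item C3: `[report, report + c3_window)` -- "right now"; the style
#'     says nothing about the full interval, so only a short window around
#'     the report is credited (default 1 minute)
#'   \item C4: `[stated_start, stated_end)`
#'   \item C5: as C4, from stated fields the annotator resolved across
#'     reports; this module validates them but never guesses
#'   \item C6: `[stated_start, report)`
#'   \item C7: `[report, report + duration)` -- "for the next N minutes"
#'   \item I1-I3: unreconstructable, sentinel
#' }
#' C2 events without a preceding report, and any reconstruction with
#' `end <= start`, fall back to the sentinel with a warning.
#'
#' @param events Validated event table.
#' @param c3_window Window in minutes credited to C3 events (default 1).
#' @return The table with POSIXct columns `interval_start`,
#'   `interval_end` (`NA` = sentinel).
#' @export
reconstruct_intervals <- function(events, c3_window = 1) {
  dt <- data.table::as.data.table(events)
  data.table::setorder(dt, participant_id, report_time, event_index)
  # previous distinct report time within participant
  dt[, prev_report_time := {
    u <- sort(unique(report_time))
    idx <- findInterval(as.numeric(report_time) - 0.5, as.numeric(u))
    .POSIXct(ifelse(idx >= 1L, as.numeric(u)[pmax(idx, 1L)], NA_real_), tz = "UTC")
  }, by = participant_id]
  rt <- as.numeric(dt$report_time)
  ss <- as.numeric(dt$stated_start)
  se <- as.numeric(dt$stated_end)
  du <- dt$stated_duration_min * 60
  pr <- as.numeric(dt$prev_report_time)
  start <- rep(NA_real_, nrow(dt))
  end <- rep(NA_real_, nrow(dt))
  sty <- dt$cue_style
  i <- sty == "C1"; start[i] <- rt[i] - du[i]; end[i] <- rt[i]
  i <- sty == "C2"; start[i] <- pr[i];         end[i] <- rt[i]
  i <- sty == "C3"; start[i] <- rt[i];         end[i] <- rt[i] + c3_window * 60
  i <- sty %in% c("C4", "C5"); start[i] <- ss[i]; end[i] <- se[i]
  i <- sty == "C6"; start[i] <- ss[i];         end[i] <- rt[i]
  i <- sty == "C7"; start[i] <- rt[i];         end[i] <- rt[i] + du[i]
  n_c2_orphan <- sum(sty == "C2" & is.na(pr))
  if (n_c2_orphan)
    warning(sprintf("%d C2 event(s) without a preceding report -> excluded", n_c2_orphan))
  degenerate <- !is.na(start) & !is.na(end) & end <= start
  if (any(degenerate))
    warning(sprintf("%d event(s) with reconstructed end <= start -> excluded",
                    sum(degenerate)))
  drop <- is.na(start) | is.na(end) | degenerate
  start[drop] <- NA_real_
  end[drop] <- NA_real_
  dt[, interval_start := .POSIXct(start, tz = "UTC")]
  dt[, interval_end := .POSIXct(end, tz = "UTC")]
  dt[]
}

#' Tally entry expansion into activity events
#'
#' Voice entries holding a clearly-timed series of activities are split
#' into their constituent events upstream (one row each, sharing the
#' entry's `report_time`). This tallies that expansion: with `E` entries
#' of which `k` expanded into `m` events, the event total is
#' `E - k + m`.
#'
#' @param events Event table (one row per event).
#' @return Named list: `entries_total`, `entries_expanded`,
#'   `events_from_expanded`, `events_total`, and the identity check
#'   `identity_holds`.
#' @export
expand_entries <- function(events) {
  dt <- data.table::as.data.table(events)
  per_entry <- dt[, .N, by = .(participant_id, report_time)]
  entries_total <- nrow(per_entry)
  entries_expanded <- sum(per_entry$N > 1L)
  events_from_expanded <- sum(per_entry$N[per_entry$N > 1L])
  events_total <- nrow(dt)
  list(entries_total = entries_total,
       entries_expanded = entries_expanded,
       events_from_expanded = events_from_expanded,
       events_total = events_total,
       identity_holds = events_total ==
         entries_total - entries_expanded + events_from_expanded)
}

#' Read a per-minute smartwatch wear mask
#'
#' @param path CSV with columns `participant_id`, `minute_start`, `worn`
#'   (0/1).
#' @return `data.table` with logical `worn` on the minute grid.
#' @export
read_wear_mask <- function(path) {
  dt <- data.table::fread(path)
  assert_cols(dt, c("participant_id", "minute_start", "worn"), "wear mask")
  dt[, minute_start := floor_minute(minute_start)]
  dt[, worn := as.logical(worn)]
  dt[]
}

# minutes an interval overlaps by >= coverage_seconds, as epoch seconds
overlap_minutes <- function(start, end, coverage_seconds = 30) {
  if (is.na(start) || is.na(end) || end <= start) return(numeric(0))
  first <- floor(start / 60) * 60
  cand <- seq(first, floor((end - 1e-9) / 60) * 60, by = 60)
  ov <- pmin(end, cand + 60) - pmax(start, cand)
  cand[ov >= coverage_seconds]
}

#' Apply event exclusions
#'
#' Drops events that cannot contribute to consensus, with a mutually
#' exclusive reason tally: `no_time` (unreconstructable interval),
#' `no_label` (undefined event), `both`, and `not_worn` (no smartwatch-worn
#' minute inside the interval). Events straddling a worn/unworn boundary
#' are retained and later truncated to worn minutes during projection;
#' the tally counts them under `truncated`.
#'
#' @param events Event table with reconstructed intervals.
#' @param wear_mask Wear-mask table (see [read_wear_mask()]); `NULL`
#'   disables the wear test.
#' @param coverage_seconds Minimum overlap for a minute to count
#'   (default 30, mirroring the epoch rule).
#' @return List with `events` (retained rows) and `tally` (named counts:
#'   `events_total`, `retained`, `no_time`, `no_label`, `both`,
#'   `not_worn`, `truncated`); count and fraction forms are both kept.
#' @export
apply_exclusions <- function(events, wear_mask = NULL, coverage_seconds = 30) {
  dt <- data.table::as.data.table(events)
  assert_cols(dt, c("interval_start", "interval_end", "labels"), "events")
  no_time <- is.na(dt$interval_start)
  no_label <- lengths(split_labels(dt$labels)) == 0L
  reason <- rep("retained", nrow(dt))
  reason[no_time & !no_label] <- "no_time"
  reason[!no_time & no_label] <- "no_label"
  reason[no_time & no_label] <- "both"
  truncated <- 0L
  if (!is.null(wear_mask)) {
    wm <- data.table::as.data.table(wear_mask)
    worn_key <- wm[worn == TRUE,
                   paste(participant_id, as.numeric(minute_start))]
    idx <- which(reason == "retained")
    for (k in idx) {
      mins <- overlap_minutes(as.numeric(dt$interval_start[k]),
                              as.numeric(dt$interval_end[k]), coverage_seconds)
      if (!length(mins)) { reason[k] <- "no_time"; next }
      keys <- paste(dt$participant_id[k], mins)
      n_worn <- sum(keys %in% worn_key)
      if (n_worn == 0L) reason[k] <- "not_worn"
      else if (n_worn < length(keys)) truncated <- truncated + 1L
    }
  }
  tally_counts <- c(events_total = nrow(dt),
                    retained = sum(reason == "retained"),
                    no_time = sum(reason == "no_time"),
                    no_label = sum(reason == "no_label"),
                    both = sum(reason == "both"),
                    not_worn = sum(reason == "not_worn"),
                    truncated = truncated)
  denom <- max(nrow(dt), 1L)
  list(events = dt[reason == "retained"],
       tally = list(counts = tally_counts,
                    fractions = tally_counts / denom))
}

#' Project retained events onto the minute grid
#'
#' A minute receives an event's label set when the event's interval
#' overlaps it by at least `coverage_seconds` (default 30, mirroring the
#' epoch rule). Overlapping events union their label sets. When a wear
#' mask is supplied, unworn minutes are dropped (truncation of straddling
#' events).
#'
#' @param events Retained event table (valid intervals and labels).
#' @param wear_mask Optional wear-mask table.
#' @param coverage_seconds Minimum overlap seconds (default 30).
#' @return `data.table` with `participant_id`, `minute_start`, `labels`
#'   (pipe-joined sorted set), `n_events`.
#' @export
project_to_minutes <- function(events, wear_mask = NULL, coverage_seconds = 30) {
  dt <- data.table::as.data.table(events)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(participant_id = character(),
                                  minute_start = .POSIXct(numeric(0), tz = "UTC"),
                                  labels = character(), n_events = integer()))
  }
  rows <- vector("list", nrow(dt))
  for (k in seq_len(nrow(dt))) {
    mins <- overlap_minutes(as.numeric(dt$interval_start[k]),
                            as.numeric(dt$interval_end[k]), coverage_seconds)
    if (!length(mins)) next
    rows[[k]] <- data.table::data.table(participant_id = dt$participant_id[k],
                                        minute = mins, labels = dt$labels[k])
  }
  long <- data.table::rbindlist(rows)
  if (nrow(long) == 0L) return(project_to_minutes(dt[0]))
  out <- long[, .(labels = paste(sort(unique(unlist(split_labels(labels)))),
                                 collapse = "|"),
                  n_events = .N),
              by = .(participant_id, minute)]
  out[, minute_start := .POSIXct(minute, tz = "UTC")]
  out[, minute := NULL]
  if (!is.null(wear_mask)) {
    wm <- data.table::as.data.table(wear_mask)[worn == TRUE,
                                               .(participant_id, minute_start)]
    out <- out[wm, on = c("participant_id", "minute_start"), nomatch = NULL]
  }
  out <- out[nzchar(labels)]
  data.table::setcolorder(out, c("participant_id", "minute_start", "labels",
                                 "n_events"))
  data.table::setorder(out, participant_id, minute_start)
  out[]
}
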