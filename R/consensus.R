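# Consensus triangulation: a minute earns a consensus label only when the
# smartwatch was worn, the thigh sensor produced a valid label, and that
# label is a member of the verbally reported label set for the minute.
# Everything else is dropped -- the accounting of that drop ("data
# shrinkage") is a first-class output.

#' Triangulate thigh labels with verbal label sets
#'
#' @param thigh Labeled-epoch table (see [assign_epoch_label()]).
#' @param verbal Minute-label table (see [project_to_minutes()]).
#' @param wear_mask Wear-mask table (see [read_wear_mask()]).
#' @param api Optional recognizer confidence table joined onto the frame
#'   (see [read_api_confidences()]).
#' @return A minute-frame `data.table`: `participant_id`, `minute_start`,
#'   `worn`, `thigh_label`, `verbal_labels` (pipe-set, `""` = none),
#'   `consensus_label` (leaf or sentinel), plus any recognizer confidence
#'   columns.
#' @export
triangulate <- function(thigh, verbal, wear_mask, api = NULL) {
  th <- data.table::as.data.table(thigh)
  assert_cols(th, c("participant_id", "minute_start", "label"), "thigh labels")
  if (anyDuplicated(th, by = c("participant_id", "minute_start")))
    stop("duplicate participant-minute keys in thigh labels")
  vb <- data.table::as.data.table(verbal)
  if (nrow(vb) && anyDuplicated(vb, by = c("participant_id", "minute_start")))
    stop("duplicate participant-minute keys in verbal minutes")
  wm <- data.table::as.data.table(wear_mask)
  if (anyDuplicated(wm, by = c("participant_id", "minute_start")))
    stop("duplicate participant-minute keys in wear mask")

  frames <- th[, .(participant_id, minute_start, thigh_label = label)]
  frames <- merge(frames, wm[, .(participant_id, minute_start, worn)],
                  by = c("participant_id", "minute_start"), all.x = TRUE)
  frames[is.na(worn), worn := FALSE]
  frames <- merge(frames,
                  vb[, .(participant_id, minute_start, verbal_labels = labels)],
                  by = c("participant_id", "minute_start"), all = TRUE)
  frames[is.na(verbal_labels), verbal_labels := ""]
  frames[is.na(worn), worn := FALSE]
  frames[is.na(thigh_label), thigh_label := excluded_label()]

  vsets <- split_labels(frames$verbal_labels)
  idx <- rep(seq_len(nrow(frames)), lengths(vsets))
  member <- logical(nrow(frames))
  member[idx[unlist(vsets) == frames$thigh_label[idx]]] <- TRUE
  frames[, consensus_label := ifelse(worn & thigh_label != excluded_label() & member,
                                     thigh_label, excluded_label())]
  if (!is.null(api)) {
    ap <- data.table::as.data.table(api)
    frames <- merge(frames, ap, by = c("participant_id", "minute_start"),
                    all.x = TRUE)
  }
  data.table::setorder(frames, participant_id, minute_start)
  frames[]
}

#' Shrinkage accounting across labeling stages
#'
#' Counts labelable minutes at each stage -- thigh-labeled (all), worn
#' ("IMU"), thigh-labeled on worn minutes, verbally labeled on worn
#' minutes, and consensus -- per participant and per activity, with the
#' derived retention ratios. Percentages in rendered tables are rounded
#' half-up to integers; full precision is retained here.
#'
#' @param frames Minute-frame table from [triangulate()].
#' @return An object of class `shrinkage_report`: `by_participant`,
#'   `by_activity` (`data.table`s) and `totals` (named list with counts
#'   `thigh_all`, `imu`, `thigh_on_worn`, `verbal_on_worn`, `consensus`
#'   and ratios `consensus_over_imu`, `consensus_over_verbal`,
#'   `consensus_over_thigh_on_worn`).
#' @export
shrinkage <- function(frames) {
  fr <- data.table::as.data.table(frames)
  if (nrow(fr) == 0L || length(unique(fr$participant_id)) < 1L)
    stop("frames must cover at least one participant")
  sent <- excluded_label()
  by_p <- fr[, .(thigh_all = sum(thigh_label != sent),
                 imu = sum(worn),
                 thigh_on_worn = sum(worn & thigh_label != sent),
                 verbal_on_worn = sum(worn & nzchar(verbal_labels)),
                 consensus = sum(consensus_label != sent)),
             by = participant_id]
  by_p[, consensus_over_imu := consensus / imu]
  by_p[, consensus_over_verbal := consensus / verbal_on_worn]
  by_p[, consensus_over_thigh_on_worn := consensus / thigh_on_worn]

  acts <- activity_labels()
  vsets <- split_labels(fr$verbal_labels)
  v_single <- ifelse(lengths(vsets) == 1L, vapply(vsets, function(s)
    if (length(s) == 1L) s else NA_character_, character(1)), NA_character_)
  v_class <- ifelse(!fr$worn, NA_character_,
                    ifelse(nzchar(fr$verbal_labels),
                           ifelse(is.na(v_single), "CompositeOrUndefined", v_single),
                           NA_character_))
  by_a <- data.table::rbindlist(lapply(acts, function(a) {
    data.table::data.table(
      activity = a,
      thigh_all = fr[, sum(thigh_label == a)],
      thigh_on_worn = fr[, sum(worn & thigh_label == a)],
      verbal_on_worn = sum(v_class == a, na.rm = TRUE),
      consensus = fr[, sum(consensus_label == a)])
  }))
  by_a <- rbind(by_a, data.table::data.table(
    activity = "CompositeOrUndefined", thigh_all = NA_integer_,
    thigh_on_worn = NA_integer_,
    verbal_on_worn = sum(v_class == "CompositeOrUndefined", na.rm = TRUE),
    consensus = NA_integer_))
  by_a[, retention := consensus / thigh_on_worn]

  totals <- list(thigh_all = sum(by_p$thigh_all), imu = sum(by_p$imu),
                 thigh_on_worn = sum(by_p$thigh_on_worn),
                 verbal_on_worn = sum(by_p$verbal_on_worn),
                 consensus = sum(by_p$consensus))
  totals$consensus_over_imu <- totals$consensus / totals$imu
  totals$consensus_over_verbal <- totals$consensus / totals$verbal_on_worn
  totals$consensus_over_thigh_on_worn <- totals$consensus / totals$thigh_on_worn
  structure(list(by_participant = by_p[], by_activity = by_a[], totals = totals),
            class = "shrinkage_report")
}

#' @export
print.shrinkage_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("shrinkage: %d thigh-labeled min, %d worn min, ",
                     "%d verbal min, %d consensus min\n"),
              t$thigh_all, t$imu, t$verbal_on_worn, t$consensus))
  cat(sprintf("  consensus/worn = %d%%, consensus/verbal = %d%%, consensus/thigh-on-worn = %d%%\n",
              round_half_up(100 * t$consensus_over_imu),
              round_half_up(100 * t$consensus_over_verbal),
              round_half_up(100 * t$consensus_over_thigh_on_worn)))
  invisible(x)
}

#' Thigh-vs-verbal confusion matrix
#'
#' Minute counts of thigh labels (rows) against verbal labels (columns),
#' restricted to worn minutes where both sources labeled the minute.
#' By default only singleton verbal reports are counted (composite sets
#' have no unique column). Rows are normalized by the thigh (row) totals.
#'
#' @param frames Minute-frame table.
#' @param singleton_only Keep only minutes whose verbal set has exactly
#'   one label (default `TRUE`).
#' @return List with `counts` and row-normalized `proportions` matrices
#'   (thigh x verbal), or, when no qualifying minutes exist, the same
#'   shape with an attribute `no_data = TRUE`.
#' @export
confusion <- function(frames, singleton_only = TRUE) {
  fr <- data.table::as.data.table(frames)
  sent <- excluded_label()
  acts <- activity_labels()
  vsets <- split_labels(fr$verbal_labels)
  keep <- fr$worn & fr$thigh_label != sent & lengths(vsets) >= 1L
  if (singleton_only) keep <- keep & lengths(vsets) == 1L
  counts <- matrix(0L, length(acts), length(acts), dimnames = list(acts, acts))
  if (any(keep)) {
    if (singleton_only) {
      tab <- table(factor(fr$thigh_label[keep], acts),
                   factor(unlist(vsets[keep]), acts))
      counts <- counts + unclass(tab)
    } else {
      for (k in which(keep)) {
        counts[fr$thigh_label[k], vsets[[k]]] <-
          counts[fr$thigh_label[k], vsets[[k]]] + 1L
      }
    }
  }
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, NA_real_, rs)
  out <- list(counts = counts, proportions = props)
  if (!any(keep)) attr(out, "no_data") <- TRUE
  out
}

#' Render shrinkage and confusion artifacts to files
#'
#' Writes `table5.csv` (per-participant stages and agreement),
#' `table6.csv` (per-activity stages and retention), `confusion.csv`
#' (counts with row proportions) and `summary.json` (machine-readable
#' totals). Percent columns are rounded half-up to integers, matching
#' report conventions.
#'
#' @param report A [shrinkage()] report.
#' @param matrix_ A [confusion()] result, or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
render_tables <- function(report, matrix_ = NULL, dir = ".") {
  stopifnot(inherits(report, "shrinkage_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(table5 = file.path(dir, "table5.csv"),
             table6 = file.path(dir, "table6.csv"),
             confusion = file.path(dir, "confusion.csv"),
             summary = file.path(dir, "summary.json"))
  t5 <- data.table::copy(report$by_participant)
  t5[, agreement_pct := round_half_up(100 * consensus_over_verbal)]
  data.table::fwrite(t5, paths[["table5"]])
  t6 <- data.table::copy(report$by_activity)
  t6[, retention_pct := round_half_up(100 * retention)]
  data.table::fwrite(t6, paths[["table6"]])
  if (!is.null(matrix_)) {
    cm <- data.table::as.data.table(matrix_$counts, keep.rownames = "thigh_label")
    data.table::fwrite(cm, paths[["confusion"]])
  }
  jsonlite::write_json(report$totals, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
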