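# Thigh-worn sensor epochs: the >30 s majority rule on per-minute
# activity-second compositions, duration derivation for labels the export
# does not provide directly, and cadence-based stepping intensity.

THIGH_EPOCH_COLS <- c("participant_id", "minute_start", "sedentary_s",
                      "sitting_transport_s", "lying_primary_s",
                      "lying_secondary_s", "upright_s", "stepping_s",
                      "cycling_s", "steps", "met")

# leaf-duration columns produced by derive_durations(), in scheme order
LEAF_DURATION_COLS <- c(
  Lying                 = "lying_s",
  SittingNotInTransport = "sitting_not_transport_s",
  SittingInTransport    = "sitting_transport_s",
  Standing              = "standing_s",
  Stepping              = "stepping_s",   # refined by cadence thresholds
  Cycling               = "cycling_s"
)

#' Read a thigh-sensor epoch table
#'
#' Expects the simplified epoch-export schema: one row per
#' participant-minute with per-class seconds, a step count and an optional
#' MET estimate. The native binary / events formats of the sensor are out
#' of scope; exports must be converted to this CSV layout first.
#'
#' @param path CSV file with columns `participant_id`, `minute_start`
#'   (ISO-8601), `sedentary_s`, `sitting_transport_s`, `lying_primary_s`,
#'   `lying_secondary_s`, `upright_s`, `stepping_s`, `cycling_s`, `steps`,
#'   `met`.
#' @return A `data.table` with `minute_start` parsed to POSIXct (UTC) and
#'   floored to the minute grid.
#' @export
read_thigh_epochs <- function(path) {
  dt <- data.table::fread(path)
  assert_cols(dt, setdiff(THIGH_EPOCH_COLS, "met"), "epoch table")
  if (!"met" %in% names(dt)) dt[, met := NA_real_]
  dt[, minute_start := floor_minute(minute_start)]
  validate_thigh_epochs(dt)
}

#' Validate epoch-record invariants
#'
#' Checks that every duration lies in `[0, 60]`, that umbrella durations
#' dominate their sub-durations (`sedentary >= sitting-in-transport`,
#' `upright >= stepping + cycling`) and that accounted seconds do not
#' exceed 60 beyond a 1 s rounding tolerance.
#'
#' @param epochs Epoch table (see [read_thigh_epochs()]).
#' @param tol Rounding tolerance in seconds (default 1).
#' @return The validated table, invisibly on success.
#' @export
validate_thigh_epochs <- function(epochs, tol = 1) {
  epochs <- data.table::as.data.table(epochs)
  assert_cols(epochs, setdiff(THIGH_EPOCH_COLS, "met"), "epoch table")
  sec_cols <- grep("_s$", names(epochs), value = TRUE)
  rng <- epochs[, sapply(.SD, function(x) any(x < 0 | x > 60)), .SDcols = sec_cols]
  if (any(rng)) stop("durations outside [0, 60] s in columns: ",
                     paste(sec_cols[rng], collapse = ", "))
  if (epochs[, any(sedentary_s < sitting_transport_s - tol)])
    stop("sedentary seconds < sitting-in-transport seconds")
  if (epochs[, any(upright_s < stepping_s + cycling_s - tol)])
    stop("upright seconds < stepping + cycling seconds")
  tot <- epochs[, sedentary_s + lying_primary_s + lying_secondary_s + upright_s]
  if (any(tot > 60 + tol)) stop("accounted seconds exceed 60 (+tolerance)")
  if (any(epochs$steps < 0)) stop("negative step counts")
  epochs
}

#' Derive durations for labels the export does not provide directly
#'
#' Three leaf labels are inferred from umbrella classes: lying is the sum
#' of the primary and secondary lying channels; sitting not in transport
#' is sedentary minus seated-transport time; standing is upright minus
#' stepping and cycling time. Small negative remainders (sensor rounding)
#' are clamped to zero; remainders below `-tol` flag the record invalid
#' rather than being silently fixed.
#'
#' @param epochs Epoch table.
#' @param tol Clamping tolerance in seconds (default 1).
#' @return The table with added columns `lying_s`,
#'   `sitting_not_transport_s`, `standing_s`, logical `invalid`, and an
#'   attribute `n_clamped` counting clamped cells.
#' @export
derive_durations <- function(epochs, tol = 1) {
  dt <- data.table::as.data.table(epochs)
  dt[, lying_s := lying_primary_s + lying_secondary_s]
  dt[, sitting_not_transport_s := sedentary_s - sitting_transport_s]
  dt[, standing_s := upright_s - stepping_s - cycling_s]
  neg <- c("sitting_not_transport_s", "standing_s")
  invalid <- rep(FALSE, nrow(dt))
  n_clamped <- 0L
  for (col in neg) {
    v <- dt[[col]]
    invalid <- invalid | (v < -tol)
    clamp <- v < 0 & v >= -tol
    n_clamped <- n_clamped + sum(clamp)
    data.table::set(dt, j = col, value = pmax(v, 0))
  }
  if (n_clamped > 0)
    warning(sprintf("clamped %d negative derived durations (within %g s rounding)",
                    n_clamped, tol))
  dt[, invalid := invalid]
  data.table::setattr(dt, "n_clamped", n_clamped)
  dt[]
}

#' Classify stepping intensity from cadence
#'
#' Personalized thresholds split stepping minutes into Low, Moderate and
#' Vigorous by cadence (steps/min). The boundary is inclusive on the
#' higher-intensity side: `steps >= theta` promotes. When the
#' moderate-vigorous threshold is absent (participant never ran), any
#' cadence at or above `theta_LM` is Moderate.
#'
#' @param steps Numeric vector of per-minute step counts (cadence).
#' @param theta_LM Low-to-moderate threshold(s), steps/min.
#' @param theta_MV Moderate-to-vigorous threshold(s), steps/min; `NA` if
#'   absent.
#' @return Character vector in `{LowStepping, ModerateStepping,
#'   VigorousStepping}`.
#' @export
classify_stepping_intensity <- function(steps, theta_LM, theta_MV = NA_real_) {
  if (any(steps < 0, na.rm = TRUE)) stop("negative step counts")
  if (any(is.na(theta_LM))) stop("theta_LM is required for stepping minutes")
  n <- length(steps)
  theta_LM <- rep_len(theta_LM, n)
  theta_MV <- rep_len(theta_MV, n)
  out <- rep("LowStepping", n)
  out[steps >= theta_LM] <- "ModerateStepping"
  out[!is.na(theta_MV) & steps >= theta_MV] <- "VigorousStepping"
  out
}

#' Assign one label per minute by the >30 s rule
#'
#' Each epoch receives the unique leaf label whose derived duration
#' strictly exceeds 30 of the 60 seconds; at most one leaf can satisfy
#' this. Minutes where no activity exceeds 30 s (alternating activities)
#' are excluded via the sentinel. A stepping win is refined into an
#' intensity sub-label using the participant's cadence thresholds.
#'
#' @param epochs Epoch table (durations derived automatically if absent).
#' @param thresholds Cadence threshold table with columns
#'   `participant_id`, `theta_LM`, `theta_MV` (NA when absent). Required
#'   only when stepping minutes occur.
#' @param rule_seconds Majority rule cutoff, strictly exceeded (default 30).
#' @return A `data.table` with `participant_id`, `minute_start`, `label`
#'   (leaf or [excluded_label()]), `basis_seconds`, `steps`.
#' @export
assign_epoch_label <- function(epochs, thresholds = NULL, rule_seconds = 30) {
  dt <- data.table::as.data.table(epochs)
  if (!"standing_s" %in% names(dt)) dt <- derive_durations(dt)
  leaf_cols <- unname(LEAF_DURATION_COLS)
  mat <- as.matrix(dt[, leaf_cols, with = FALSE])
  over <- mat > rule_seconds
  n_over <- rowSums(over)
  if (any(n_over > 1))
    stop("internal consistency failure: two activities each exceed ",
         rule_seconds, " s within one minute")
  win <- max.col(mat, ties.method = "first")
  label <- names(LEAF_DURATION_COLS)[win]
  basis <- mat[cbind(seq_len(nrow(mat)), win)]
  label[n_over == 0L] <- excluded_label()
  basis[n_over == 0L] <- NA_real_
  if ("invalid" %in% names(dt)) {
    label[dt$invalid] <- excluded_label()
    basis[dt$invalid] <- NA_real_
  }
  out <- dt[, .(participant_id, minute_start, steps)]
  out[, label := label]
  out[, basis_seconds := basis]
  step_idx <- which(out$label == "Stepping")
  if (length(step_idx)) {
    if (is.null(thresholds))
      stop("stepping minutes present but no cadence thresholds supplied")
    th <- data.table::as.data.table(thresholds)
    assert_cols(th, c("participant_id", "theta_LM"), "threshold table")
    if (!"theta_MV" %in% names(th)) th[, theta_MV := NA_real_]
    pos <- match(out$participant_id[step_idx], th$participant_id)
    lm <- th$theta_LM[pos]
    if (anyNA(lm))
      stop("missing cadence thresholds for participants: ",
           paste(unique(out$participant_id[step_idx][is.na(lm)]), collapse = ", "))
    refined <- classify_stepping_intensity(out$steps[step_idx], lm, th$theta_MV[pos])
    data.table::set(out, i = step_idx, j = "label", value = refined)
  }
  data.table::setcolorder(out, c("participant_id", "minute_start", "label",
                                 "basis_seconds", "steps"))
  out[]
}

#' Fraction of excluded epochs
#'
#' @param labels Labeled-epoch table or character vector of labels.
#' @return Fraction of sentinel labels in `[0, 1]`.
#' @export
exclusion_rate <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  if (length(labels) == 0L) stop("empty label collection")
  mean(labels == excluded_label())
}

#' Write a labeled-epoch table
#'
#' @param labels Output of [assign_epoch_label()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_epoch_labels <- function(labels, path) {
  out <- data.table::as.data.table(labels)
  out <- out[, .(participant_id, minute_start = format_minute(minute_start),
                 label, basis_seconds)]
  data.table::fwrite(out, path)
  invisible(path)
}
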