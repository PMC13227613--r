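# Per-participant stepping cadence distributions and personalized
# intensity thresholds. The original thresholds were set by visual
# inspection of per-participant cadence histograms (2 steps/min bins, KDE
# overlay, epochs under 50 steps dropped); this module automates the
# peak/valley reading and also accepts a manual threshold file verbatim.

#' Build a stepping cadence profile for one participant
#'
#' Histograms the cadence (steps/min) of stepping epochs in fixed-width
#' bins and overlays a Gaussian kernel density estimate. Epochs below
#' `min_steps` are excluded before both the histogram and the density (the
#' low tail is dominated by partial stepping minutes).
#'
#' @param steps Numeric vector of per-epoch step counts.
#' @param participant_id Identifier carried into the profile.
#' @param bin_width Histogram bin width in steps/min (default 2).
#' @param min_steps Exclusion cutoff in steps/min (default 50); epochs with
#'   strictly fewer steps are dropped.
#' @param apply_filter_to_density If `FALSE`, the `min_steps` filter only
#'   affects the histogram, not the density (default `TRUE`).
#' @param bw Kernel bandwidth; default Silverman's rule on the filtered
#'   cadences (`stats::bw.nrd0`).
#' @return An object of class `cadence_profile`: participant id, bin
#'   `breaks` and `counts`, `density` (list with `x`, `y`), `n_epochs`,
#'   and unset thresholds `theta_LM`, `theta_MV`.
#' @export
cadence_profile <- function(steps, participant_id = "P?", bin_width = 2,
                            min_steps = 50, apply_filter_to_density = TRUE,
                            bw = NULL) {
  stopifnot(is.numeric(steps), bin_width > 0)
  kept <- steps[steps >= min_steps]
  if (length(kept) == 0L)
    stop(sprintf("no stepping epochs remain after the >= %g steps/min filter",
                 min_steps))
  breaks <- seq(floor(min(kept) / bin_width) * bin_width,
                ceiling((max(kept) + 1e-9) / bin_width) * bin_width + bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(kept, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  dens_in <- if (apply_filter_to_density) kept else steps
  if (is.null(bw)) bw <- stats::bw.nrd0(dens_in)
  d <- stats::density(dens_in, bw = bw, n = 512)
  structure(list(participant_id = participant_id,
                 breaks = breaks, counts = counts,
                 density = list(x = d$x, y = d$y), bw = bw,
                 bin_width = bin_width, min_steps = min_steps,
                 n_epochs = length(kept),
                 theta_LM = NA_real_, theta_MV = NA_real_,
                 indeterminate = NA),
            class = "cadence_profile")
}

#' @export
print.cadence_profile <- function(x, ...) {
  cat(sprintf("cadence profile for %s: %d stepping epochs, support [%g, %g] steps/min\n",
              x$participant_id, x$n_epochs, min(x$breaks), max(x$breaks)))
  if (!is.na(x$theta_LM))
    cat(sprintf("  theta_LM = %.1f%s steps/min\n", x$theta_LM,
                if (is.na(x$theta_MV)) "" else sprintf(", theta_MV = %.1f", x$theta_MV)))
  if (isTRUE(x$indeterminate)) cat("  indeterminate: fewer than 2 density peaks\n")
  invisible(x)
}

#' Local density maxima with a prominence floor
#'
#' A peak's prominence is its height minus the higher of the two minima
#' separating it from higher ground on each side (the usual topographic
#' definition). Peaks with prominence below `min_prominence * max(y)` are
#' discarded.
#'
#' @param x,y Density grid and values.
#' @param min_prominence Fraction of the maximum density (default 0.05).
#' @return Integer vector of peak indices into `x`, in position order.
#' @export
find_density_peaks <- function(x, y, min_prominence = 0.05) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left_higher <- which(y[seq_len(i - 1L)] > h)
    lo_l <- if (length(left_higher)) min(y[(max(left_higher) + 1L):(i - 1L)]) else min(y[seq_len(i)])
    right_higher <- which(y[(i + 1L):n] > h) + i
    lo_r <- if (length(right_higher)) min(y[(i + 1L):(min(right_higher) - 1L)]) else min(y[i:n])
    h - max(lo_l, lo_r)
  }, numeric(1))
  cand[prom >= min_prominence * max(y)]
}

#' Estimate personalized cadence thresholds from density peaks
#'
#' Detects up to three prominent peaks in the cadence density
#' (low/moderate/vigorous stepping modes) and places each threshold at the
#' density minimum (valley) between adjacent accepted peaks; equal-depth
#' valleys break toward the leftmost grid point. Two peaks yield only
#' `theta_LM`; a single peak flags the profile indeterminate (no automated
#' thresholds; supply manual ones). If more than three peaks pass the
#' prominence floor, the three most prominent are kept.
#'
#' @param profile A [cadence_profile()].
#' @param min_prominence Peak prominence floor as a fraction of the
#'   maximum density (default 0.05).
#' @return The profile with `theta_LM` / `theta_MV` set (`theta_MV` `NA`
#'   when only two modes exist) and `indeterminate` resolved; peak
#'   positions are stored in `$peaks`.
#' @export
estimate_thresholds <- function(profile, min_prominence = 0.05) {
  stopifnot(inherits(profile, "cadence_profile"))
  x <- profile$density$x
  y <- profile$density$y
  pk <- find_density_peaks(x, y, min_prominence)
  if (length(pk) > 3L) {
    # keep the 3 tallest, in position order
    pk <- sort(pk[order(y[pk], decreasing = TRUE)][1:3])
  }
  profile$peaks <- x[pk]
  if (length(pk) <= 1L) {
    profile$indeterminate <- TRUE
    profile$theta_LM <- NA_real_
    profile$theta_MV <- NA_real_
    return(profile)
  }
  valley <- function(i, j) {
    seg <- seq(i, j)
    x[seg[which.min(y[seg])]]       # which.min: leftmost at ties
  }
  profile$indeterminate <- FALSE
  profile$theta_LM <- valley(pk[1], pk[2])
  profile$theta_MV <- if (length(pk) >= 3L) valley(pk[2], pk[3]) else NA_real_
  profile
}

#' Read a manual cadence-threshold file
#'
#' Manual thresholds (e.g. set by a kinesiologist from visual inspection)
#' are authoritative when present; blank or `-` entries mean the
#' participant has no moderate-vigorous boundary.
#'
#' @param path CSV with columns `participant_id`, `theta_LM`, `theta_MV`.
#' @return `data.table` with numeric thresholds (`theta_MV` may be `NA`).
#' @export
read_thresholds <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  assert_cols(dt, c("participant_id", "theta_LM"), "threshold file")
  if (!"theta_MV" %in% names(dt)) dt[, theta_MV := NA_real_]
  for (col in c("theta_LM", "theta_MV")) {
    v <- dt[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(ifelse(v %in% c("-", ""), NA, v)))
    data.table::set(dt, j = col, value = as.numeric(v))
  }
  if (any(!is.na(dt$theta_MV) & dt$theta_MV <= dt$theta_LM))
    stop("theta_MV must exceed theta_LM")
  dt[]
}

#' Threshold table for a set of profiles
#'
#' @param profiles List of [cadence_profile()] objects (thresholds set).
#' @param manual Optional manual threshold table; rows present there
#'   override the automated estimates verbatim.
#' @return `data.table` with `participant_id`, `theta_LM`, `theta_MV`,
#'   `source` (`manual` or `estimated`).
#' @export
threshold_table <- function(profiles, manual = NULL) {
  est <- data.table::rbindlist(lapply(profiles, function(p) {
    if (isTRUE(p$indeterminate) && is.null(manual))
      stop(sprintf("profile %s is indeterminate and no manual thresholds were supplied",
                   p$participant_id))
    data.table::data.table(participant_id = p$participant_id,
                           theta_LM = p$theta_LM, theta_MV = p$theta_MV,
                           source = "estimated")
  }))
  if (!is.null(manual)) {
    man <- data.table::as.data.table(manual)[, .(participant_id,
                                                 theta_LM, theta_MV,
                                                 source = "manual")]
    est <- rbind(man, est[!participant_id %in% man$participant_id])
  }
  bad <- est[is.na(theta_LM), participant_id]
  if (length(bad))
    stop("no usable thresholds for participants: ", paste(bad, collapse = ", "))
  est[]
}

# keyword lexicon for perceived exertion; deliberately short and fixed --
# free-text keyword extraction is known to be unreliable for this cohort
EXERTION_LEXICON <- list(
  VigorousStepping = c("run", "ran", "running", "intense"),
  ModerateStepping = c("moderate", "moderately", "steady", "brisk", "medium")
)

#' Audit thresholds against verbally reported exertion
#'
#' Cross-checks estimated thresholds against participants' own exertion
#' language: each audited item pairs an exertion phrase with the cadence
#' range of its overlapping stepping epochs. The phrase implies a class
#' via a fixed keyword lexicon; the thresholds imply a class via the range
#' midpoint; the audit reports whether they match.
#'
#' @param items `data.frame` with columns `participant_id`, `phrase`,
#'   `cadence_min`, `cadence_max` (steps/min).
#' @param thresholds Threshold table (see [threshold_table()]).
#' @return `data.table` of auditable items with `implied_class`,
#'   `threshold_class`, `consistent`; attribute `agreement` holds the
#'   agreement fraction (`NA` when no item carries a lexicon keyword).
#' @export
exertion_audit <- function(items, thresholds) {
  items <- data.table::as.data.table(items)
  if (nrow(items) == 0L) {
    out <- data.table::data.table(participant_id = character(),
                                  phrase = character(),
                                  cadence_min = numeric(), cadence_max = numeric(),
                                  implied_class = character(),
                                  threshold_class = character(),
                                  consistent = logical())
    data.table::setattr(out, "agreement", NA_real_)
    return(out)
  }
  assert_cols(items, c("participant_id", "phrase", "cadence_min", "cadence_max"),
              "exertion items")
  if (any(items$cadence_min > items$cadence_max))
    stop("cadence range min exceeds max")
  th <- data.table::as.data.table(thresholds)
  implied <- vapply(tolower(items$phrase), function(txt) {
    words <- strsplit(txt, "[^a-z]+")[[1]]
    for (cls in names(EXERTION_LEXICON)) {
      if (any(words %in% EXERTION_LEXICON[[cls]])) return(cls)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  items[, implied_class := implied]
  pos <- match(items$participant_id, th$participant_id)
  if (anyNA(pos)) stop("exertion items reference participants without thresholds")
  mid <- (items$cadence_min + items$cadence_max) / 2
  items[, threshold_class := classify_stepping_intensity(mid, th$theta_LM[pos],
                                                         th$theta_MV[pos])]
  items[, consistent := !is.na(implied_class) & implied_class == threshold_class]
  keyed <- !is.na(items$implied_class)
  data.table::setattr(items, "agreement",
                      if (any(keyed)) mean(items$consistent[keyed]) else NA_real_)
  items[]
}

#' Build exertion-audit items from events and labeled epochs
#'
#' Selects stepping-labeled verbal events with valid intervals and
#' attaches the cadence range (min/max steps) of the stepping epochs they
#' overlap; events overlapping no stepping epoch are skipped with a
#' warning.
#'
#' @param events Event table with reconstructed intervals and `raw_text`.
#' @param epoch_labels Labeled-epoch table (see [assign_epoch_label()]).
#' @return Item table for [exertion_audit()].
#' @export
exertion_items <- function(events, epoch_labels) {
  ev <- data.table::as.data.table(events)
  el <- data.table::as.data.table(epoch_labels)
  stepping <- c("LowStepping", "ModerateStepping", "VigorousStepping")
  sets <- split_labels(ev$labels)
  keep <- vapply(sets, function(s) any(s %in% stepping), logical(1)) &
    !is.na(ev$interval_start)
  ev <- ev[keep]
  st <- el[label %in% stepping]
  rows <- vector("list", nrow(ev))
  n_skip <- 0L
  for (k in seq_len(nrow(ev))) {
    m <- st[participant_id == ev$participant_id[k] &
              as.numeric(minute_start) >= as.numeric(ev$interval_start[k]) &
              as.numeric(minute_start) < as.numeric(ev$interval_end[k])]
    if (nrow(m) == 0L) { n_skip <- n_skip + 1L; next }
    rows[[k]] <- data.table::data.table(
      participant_id = ev$participant_id[k],
      phrase = if ("raw_text" %in% names(ev)) ev$raw_text[k] else "",
      cadence_min = min(m$steps), cadence_max = max(m$steps))
  }
  if (n_skip) warning(sprintf("%d stepping event(s) without overlapping stepping epochs skipped",
                              n_skip))
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(participant_id = character(),
                                  phrase = character(),
                                  cadence_min = numeric(),
                                  cadence_max = numeric())
  }
  out[]
}
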