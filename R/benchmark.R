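# Benchmarking a per-minute activity recognizer (confidence 0-100 per
# class) against the thigh-only, verbal-only and consensus label sources:
# one-vs-rest ROC per class, Youden-optimal operating points, rank-based
# AUC, and false-positive / false-negative cross-tabulations.

API_CONF_COLS <- c("still", "in_vehicle", "on_foot", "walking", "running",
                   "on_bicycle", "tilting", "unknown")

conf_col <- function(api_class) tolower(api_class)

#' Read a recognizer confidence table
#'
#' @param path CSV with columns `participant_id`, `minute_start` and one
#'   confidence column (0-100) per recognizer class: `r
#'   paste(API_CONF_COLS, collapse = ", ")`.
#' @return `data.table` on the minute grid.
#' @export
read_api_confidences <- function(path) {
  dt <- data.table::fread(path)
  assert_cols(dt, c("participant_id", "minute_start", API_CONF_COLS),
              "confidence table")
  dt[, minute_start := floor_minute(minute_start)]
  for (col in API_CONF_COLS) {
    v <- dt[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("confidences outside [0, 100] in column ", col)
  }
  dt[]
}

#' Per-minute binary truth for one recognizer class under one label source
#'
#' A minute is a positive when the source's label -- or, for the verbal
#' source, any member of its label set -- belongs to the class's mapped
#' leaf set ([api_label_set()]). Minutes the source did not label are
#' omitted, so different sources evaluate on different minute sets; that
#' is the label-source effect this tool exposes, and `n` is always
#' reported downstream.
#'
#' @param frames Minute-frame table with recognizer confidences joined.
#' @param api_class Recognizer class; must have a non-empty mapped set.
#' @param label_source One of `"thigh"`, `"verbal"`, `"consensus"`.
#' @return `data.table` with keys, `confidence` and integer `truth`.
#' @export
binarize_truth <- function(frames, api_class, label_source = c("consensus", "thigh", "verbal")) {
  label_source <- match.arg(label_source)
  pos_set <- api_label_set(api_class)
  if (length(pos_set) == 0L)
    stop(sprintf("class '%s' maps to the empty set and is not evaluable", api_class))
  fr <- data.table::as.data.table(frames)
  col <- conf_col(api_class)
  assert_cols(fr, col, "frames (confidences)")
  sent <- excluded_label()
  keep <- fr$worn & !is.na(fr[[col]])
  truth <- switch(label_source,
    thigh = {
      keep <- keep & fr$thigh_label != sent
      fr$thigh_label %in% pos_set
    },
    consensus = {
      keep <- keep & fr$consensus_label != sent
      fr$consensus_label %in% pos_set
    },
    verbal = {
      sets <- split_labels(fr$verbal_labels)
      keep <- keep & lengths(sets) > 0L
      idx <- rep(seq_len(nrow(fr)), lengths(sets))
      hit <- logical(nrow(fr))
      hit[idx[unlist(sets) %in% pos_set]] <- TRUE
      hit
    })
  out <- fr[keep, .(participant_id, minute_start)]
  out[, confidence := fr[[col]][keep]]
  out[, truth := as.integer(truth[keep])]
  out[]
}

#' ROC points by threshold sweep
#'
#' Standard sweep over the distinct confidence values (prediction positive
#' when `confidence >= threshold`), ties grouped, from `(0, 0)` at
#' `threshold = Inf` to `(1, 1)`.
#'
#' @param confidence Numeric scores.
#' @param truth 0/1 vector.
#' @return `data.table` with `threshold`, `fpr`, `tpr`, ordered by
#'   decreasing threshold (both coordinates non-decreasing).
#' @export
roc_points <- function(confidence, truth) {
  stopifnot(length(confidence) == length(truth))
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop(sprintf("single-class truth (%d positives, %d negatives): ROC undefined",
                 n_pos, n_neg))
  o <- order(confidence, decreasing = TRUE)
  cs_pos <- cumsum(truth[o] == 1L)
  cs_neg <- cumsum(truth[o] == 0L)
  last <- rev(!duplicated(rev(confidence[o])))   # last index of each tie group
  data.table::data.table(
    threshold = c(Inf, confidence[o][last]),
    fpr = c(0, cs_neg[last] / n_neg),
    tpr = c(0, cs_pos[last] / n_pos))
}

#' Youden-optimal operating point
#'
#' Maximizes Youden's J = TPR - FPR over the swept thresholds; ties break
#' toward the highest threshold (the most conservative detector).
#'
#' @param roc Output of [roc_points()].
#' @return Named list with `threshold` and `J`.
#' @export
youden_optimal <- function(roc, tol = 1e-12) {
  j <- roc$tpr - roc$fpr
  best <- max(j)
  # roc is ordered by decreasing threshold: the first index within `tol`
  # of the maximum wins, so exact-rational ties (e.g. equal J from
  # different count pairs) break toward the higher threshold even when
  # floating-point rounding separates them by an ulp
  k <- which(j >= best - tol)[1L]
  list(threshold = roc$threshold[k], J = j[k])
}

#' Rank-based AUC with tie correction
#'
#' The Mann-Whitney form: the probability a random positive outranks a
#' random negative, ties counted half. Equals the trapezoidal area under
#' the grouped ROC curve.
#'
#' @param confidence Numeric scores.
#' @param truth 0/1 vector with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(confidence, truth) {
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("single-class truth: AUC undefined")
  r <- rank(confidence)             # midranks handle ties
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full evaluation curve for one class and source
#'
#' @param frames Minute-frame table with confidences.
#' @param api_class Recognizer class.
#' @param label_source Label source (see [binarize_truth()]).
#' @return Object of class `eval_curve`: roc points, Youden threshold and
#'   J, AUC, and `n_pos` / `n_neg`.
#' @export
eval_curve <- function(frames, api_class, label_source = "consensus") {
  b <- binarize_truth(frames, api_class, label_source)
  roc <- roc_points(b$confidence, b$truth)
  yj <- youden_optimal(roc)
  structure(list(api_class = api_class, label_source = label_source,
                 roc = roc, youden_threshold = yj$threshold, youden_J = yj$J,
                 auc = auc_score(b$confidence, b$truth),
                 n_pos = sum(b$truth == 1L), n_neg = sum(b$truth == 0L)),
            class = "eval_curve")
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("%s vs %s labels: AUC = %.3f, Youden J = %.3f at threshold %.4g (n+ = %d, n- = %d)\n",
              x$api_class, x$label_source, x$auc, x$youden_J,
              x$youden_threshold, x$n_pos, x$n_neg))
  invisible(x)
}

#' AUC grid across classes and label sources
#'
#' AUC per evaluable recognizer class under each of the three label
#' sources, computed on raw confidences. Minutes unlabeled under a source
#' are excluded for that source only. Cells whose truth is single-class
#' are marked not-evaluable and the run continues.
#'
#' @param frames Minute-frame table with confidences.
#' @param classes Recognizer classes (default: all evaluable).
#' @param sources Label sources (default all three).
#' @return `data.table` with `api_class`, `label_source`, `auc`,
#'   `n_pos`, `n_neg`, logical `evaluable`.
#' @export
compare_sources <- function(frames,
                            classes = api_classes(evaluable = TRUE),
                            sources = c("thigh", "verbal", "consensus")) {
  grid <- data.table::CJ(api_class = classes, label_source = sources,
                         sorted = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cls <- grid$api_class[k]; src <- grid$label_source[k]
    b <- binarize_truth(frames, cls, src)
    n_pos <- sum(b$truth == 1L); n_neg <- sum(b$truth == 0L)
    ok <- n_pos > 0L && n_neg > 0L
    data.table::data.table(api_class = cls, label_source = src,
                           auc = if (ok) auc_score(b$confidence, b$truth) else NA_real_,
                           n_pos = n_pos, n_neg = n_neg, evaluable = ok)
  })
  data.table::rbindlist(rows)
}

#' FP/FN cross-tabulation of thresholded detections vs consensus labels
#'
#' For each audited class, confidences are thresholded at the class's
#' Youden-optimal operating point (computed against consensus truth unless
#' supplied), and detected / not-detected minute counts are tabulated per
#' consensus label. Off-target detections (e.g. `IN_VEHICLE` detected
#' while the consensus says Standing) are the false-positive cells.
#'
#' @param frames Minute-frame table with confidences.
#' @param classes Classes to audit (default `IN_VEHICLE` and `STILL`).
#' @param thresholds Optional named numeric vector of fixed thresholds.
#' @return `data.table` with `consensus_label` rows and, per class,
#'   `<class>_detected` / `<class>_not_detected` counts.
#' @export
error_crosstab <- function(frames, classes = c("IN_VEHICLE", "STILL"),
                           thresholds = NULL) {
  fr <- data.table::as.data.table(frames)
  sent <- excluded_label()
  acts <- activity_labels()
  keep <- fr$worn & fr$consensus_label != sent
  out <- data.table::data.table(consensus_label = acts)
  for (cls in classes) {
    col <- conf_col(cls)
    assert_cols(fr, col, "frames (confidences)")
    thr <- if (!is.null(thresholds) && cls %in% names(thresholds)) {
      thresholds[[cls]]
    } else {
      ec <- eval_curve(fr, cls, "consensus")
      ec$youden_threshold
    }
    rows_keep <- keep & !is.na(fr[[col]])
    det <- fr[[col]] >= thr
    lab <- factor(fr$consensus_label[rows_keep], acts)
    out[, paste0(cls, "_detected") := as.integer(table(lab[det[rows_keep]]))]
    out[, paste0(cls, "_not_detected") := as.integer(table(lab[!det[rows_keep]]))]
  }
  out[]
}
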