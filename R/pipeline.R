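# End-to-end driver: from the four input tables to consensus frames,
# shrinkage accounting and recognizer benchmark, plus a small CLI.

#' Run the full consensus-labeling pipeline
#'
#' Epoch labeling (with cadence thresholds estimated from the epoch table
#' itself when not supplied), verbal interval reconstruction, exclusions,
#' minute projection, triangulation, shrinkage and confusion accounting,
#' and (when confidences are given) the recognizer benchmark.
#'
#' @param thigh_epochs Epoch table (see [read_thigh_epochs()]).
#' @param verbal_events Event table (see [read_verbal_events()]).
#' @param wear_mask Wear-mask table (see [read_wear_mask()]).
#' @param api Optional confidence table (see [read_api_confidences()]).
#' @param thresholds Optional manual cadence-threshold table; estimated
#'   per participant from the epoch table when `NULL`.
#' @param c3_window C3 reconstruction window, minutes (default 1).
#' @param coverage_seconds Minute-coverage rule, seconds (default 30).
#' @param min_steps Cadence-profile filter, steps/min (default 50).
#' @return List with `thigh_labels`, `thresholds`, `verbal_minutes`,
#'   `exclusion_tally`, `frames`, `shrinkage`, `confusion`, and `auc`
#'   (`NULL` without confidences).
#' @export
run_pipeline <- function(thigh_epochs, verbal_events, wear_mask, api = NULL,
                         thresholds = NULL, c3_window = 1,
                         coverage_seconds = 30, min_steps = 50) {
  epochs <- derive_durations(data.table::as.data.table(thigh_epochs))
  if (is.null(thresholds)) {
    stepping <- epochs[stepping_s > 30]
    ids <- sort(unique(stepping$participant_id))
    profiles <- lapply(ids, function(pid) {
      estimate_thresholds(cadence_profile(stepping[participant_id == pid, steps],
                                          pid, min_steps = min_steps))
    })
    thresholds <- threshold_table(profiles)
  }
  thigh_labels <- assign_epoch_label(epochs, thresholds)
  ev <- reconstruct_intervals(validate_verbal_events(verbal_events),
                              c3_window = c3_window)
  excl <- apply_exclusions(ev, wear_mask, coverage_seconds = coverage_seconds)
  verbal_minutes <- project_to_minutes(excl$events, wear_mask,
                                       coverage_seconds = coverage_seconds)
  frames <- triangulate(thigh_labels, verbal_minutes, wear_mask, api = api)
  shr <- shrinkage(frames)
  conf <- confusion(frames, singleton_only = TRUE)
  auc <- if (!is.null(api)) compare_sources(frames) else NULL
  list(thigh_labels = thigh_labels, thresholds = thresholds,
       verbal_minutes = verbal_minutes, exclusion_tally = excl$tally,
       frames = frames, shrinkage = shr, confusion = conf, auc = auc)
}

parse_cli_args <- function(args) {
  out <- list()
  k <- 1L
  while (k <= length(args)) {
    if (startsWith(args[k], "--")) {
      key <- sub("^--", "", args[k])
      if (k < length(args) && !startsWith(args[k + 1L], "--")) {
        out[[key]] <- args[k + 1L]; k <- k + 2L
      } else {
        out[[key]] <- TRUE; k <- k + 1L
      }
    } else k <- k + 1L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed N --outdir DIR [--noise none]`,
#' `ingest-thigh --epochs FILE --thresholds FILE --out FILE`,
#' `thresholds --stepping FILE [--manual FILE] --out FILE`,
#' `reconstruct-verbal --events FILE --wear FILE --out FILE [--c3-window 1]`,
#' `consensus --thigh FILE --verbal FILE --wear FILE --outdir DIR`,
#' `benchmark --frames DIRofconsensus --api FILE --outdir DIR`,
#' `run-all --indir DIR --outdir DIR` (reads the four simulate outputs).
#'
#' @param args Character vector (default: the process command line).
#' @return Exit status 0, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) stop("usage: actconsensus <subcommand> [--key value ...]")
  cmd <- args[1L]
  opt <- parse_cli_args(args[-1L])
  need <- function(key) {
    if (is.null(opt[[key]])) stop(sprintf("subcommand '%s' requires --%s", cmd, key))
    opt[[key]]
  }
  switch(cmd,
    "simulate" = {
      cfg <- cohort_config(
        n_participants = as.integer(opt$participants %||% 13),
        n_days = as.integer(opt$days %||% 7),
        seed = as.integer(need("seed")),
        noise = if (isTRUE(opt$noise == "none")) "none" else "default")
      write_cohort(simulate_cohort(cfg), need("outdir"))
    },
    "ingest-thigh" = {
      epochs <- read_thigh_epochs(need("epochs"))
      th <- read_thresholds(need("thresholds"))
      write_epoch_labels(assign_epoch_label(derive_durations(epochs), th),
                         need("out"))
    },
    "thresholds" = {
      stepping <- data.table::fread(need("stepping"))
      manual <- if (!is.null(opt$manual)) read_thresholds(opt$manual)
      profiles <- lapply(unique(stepping$participant_id), function(pid) {
        estimate_thresholds(cadence_profile(
          stepping[stepping$participant_id == pid, ][["steps"]], pid))
      })
      data.table::fwrite(threshold_table(profiles, manual), need("out"))
    },
    "reconstruct-verbal" = {
      ev <- reconstruct_intervals(read_verbal_events(need("events")),
                                  c3_window = as.numeric(opt[["c3-window"]] %||% 1))
      excl <- apply_exclusions(ev, read_wear_mask(need("wear")))
      mins <- project_to_minutes(excl$events, read_wear_mask(need("wear")))
      out <- data.table::copy(mins)
      out[, minute_start := format_minute(minute_start)]
      data.table::fwrite(out, need("out"))
    },
    "consensus" = {
      res <- run_pipeline(read_thigh_epochs(need("thigh")),
                          read_verbal_events(need("verbal")),
                          read_wear_mask(need("wear")))
      render_tables(res$shrinkage, res$confusion, need("outdir"))
    },
    "run-all" = {
      indir <- need("indir")
      res <- run_pipeline(
        read_thigh_epochs(file.path(indir, "thigh_epochs.csv")),
        read_verbal_events(file.path(indir, "verbal_events.csv")),
        read_wear_mask(file.path(indir, "wear_mask.csv")),
        api = read_api_confidences(file.path(indir, "api_confidences.csv")))
      outdir <- need("outdir")
      render_tables(res$shrinkage, res$confusion, outdir)
      data.table::fwrite(res$auc, file.path(outdir, "table8.csv"))
      data.table::fwrite(error_crosstab(res$frames),
                         file.path(outdir, "table9.csv"))
    },
    stop(sprintf("unknown subcommand '%s'", cmd))
  )
  invisible(0L)
}
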