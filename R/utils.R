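# shared helpers: minute grid, rounding, validation

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Floor timestamps to the wall-clock minute grid
#'
#' The analysis unit is the half-open minute `[t, t + 60 s)`; timestamps
#' are floored to the minute, in UTC.
#'
#' @param x POSIXct vector, or character parseable as ISO-8601.
#' @return POSIXct vector on the minute grid (UTC).
#' @export
floor_minute <- function(x) {
  x <- as_utc_time(x)
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) return(.POSIXct(as.numeric(x), tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) stop("unparseable timestamps: ",
                                    paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  out
}

format_minute <- function(x) format(as_utc_time(x), "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Round half away from zero
#'
#' Report tables print integer percentages rounded half-up (5.5 -> 6),
#' unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required columns: %s", what,
                 paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# deterministic per-participant substream seeds derived from a global seed;
# adding participants never perturbs existing ones. Kept below 2^31.
substream_seed <- function(seed, participant, stream = 0L) {
  h <- (as.numeric(seed) * 2654435761 + participant * 97003 + stream * 911) %%
    2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
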