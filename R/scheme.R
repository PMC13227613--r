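#' actconsensus: consensus activity labels for free-living wearable studies
#'
#' Tools for building minute-level consensus ground-truth activity labels
#' by triangulating a thigh-worn posture sensor with verbally reported
#' activities, personalizing stepping-intensity cadence thresholds, and
#' benchmarking a per-minute activity recognizer against each label source.
#' A synthetic cohort generator reproduces the statistical structure of the
#' original 13-participant deployment so the entire pipeline runs without
#' access to the (non-public) study data.
#'
#' @import data.table
#' @importFrom stats density rgamma rnorm runif rbeta rbinom sd quantile
#' @importFrom utils read.csv write.csv head tail
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

# single cached copy of the mapping resource
.scheme_env <- new.env(parent = emptyenv())

#' Hierarchical activity scheme
#'
#' The scheme has 8 leaf activities grouped under three postural branches:
#' Sedentary (Lying, SittingNotInTransport, SittingInTransport), Upright
#' (Standing, LowStepping, ModerateStepping, VigorousStepping) and Cycling.
#' Mapping tables from the two label sources (thigh sensor export classes
#' and recognizer classes) are shipped as a JSON resource so they are
#' auditable and can be overridden.
#'
#' @param path Optional path to an alternative scheme JSON; defaults to the
#'   resource shipped with the package.
#' @return A list with elements `leaves` (named character: leaf -> parent),
#'   `thigh` and `api` (named lists of leaf-label character vectors) and
#'   `met_categories` (named numeric bounds).
#' @export
activity_scheme <- function(path = NULL) {
  if (!is.null(path)) {
    return(validate_scheme(jsonlite::read_json(path, simplifyVector = TRUE)))
  }
  if (is.null(.scheme_env$scheme)) {
    p <- system.file("extdata", "activity_scheme.json", package = "actconsensus",
                     mustWork = TRUE)
    .scheme_env$scheme <- validate_scheme(jsonlite::read_json(p, simplifyVector = TRUE))
  }
  .scheme_env$scheme
}

validate_scheme <- function(s) {
  stopifnot(is.list(s), all(c("leaves", "thigh", "api", "met_categories") %in% names(s)))
  leaves <- names(s$leaves)
  if (length(leaves) != 8L) stop("scheme must define exactly 8 leaf labels")
  for (src in c("thigh", "api")) {
    bad <- setdiff(unlist(s[[src]], use.names = FALSE), leaves)
    if (length(bad)) {
      stop(sprintf("scheme '%s' mapping uses unknown leaves: %s",
                   src, paste(bad, collapse = ", ")))
    }
  }
  s
}

#' Leaf activity labels
#'
#' @return Character vector of the 8 leaf labels, in canonical order
#'   (sedentary branch first, then upright, then cycling).
#' @export
activity_labels <- function() names(activity_scheme()$leaves)

#' Parent branch of each leaf label
#'
#' @param labels Character vector of leaf labels.
#' @return Character vector of branch names (`Sedentary`, `Upright`,
#'   `Cycling`).
#' @export
activity_parent <- function(labels) {
  leaves <- activity_scheme()$leaves
  bad <- setdiff(labels, names(leaves))
  if (length(bad)) stop("unknown activity labels: ", paste(bad, collapse = ", "))
  unname(unlist(leaves[labels]))
}

#' Sentinel for excluded epochs and events
#'
#' A distinguished non-label value carried by minutes/events dropped from
#' the analysis (no >30 s majority, unreconstructable time cues, ...). It is
#' never counted in any statistic.
#'
#' @return The sentinel string.
#' @export
excluded_label <- function() "<excluded>"

#' Map a recognizer class to its set of leaf labels
#'
#' The recognizer reports coarse classes; several of them (`STILL`,
#' `WALKING`, `ON_FOOT`) legitimately cover multiple postures of the
#' hierarchical scheme and are mapped to label *sets*. `TILTING` and
#' `UNKNOWN` carry no posture information and map to the empty set; they
#' are excluded from all evaluations.
#'
#' @param api_class One of `STILL`, `IN_VEHICLE`, `ON_FOOT`, `WALKING`,
#'   `RUNNING`, `ON_BICYCLE`, `TILTING`, `UNKNOWN`.
#' @return Character vector of leaf labels (possibly empty).
#' @export
#' @examples
#' api_label_set("RUNNING")
#' api_label_set("STILL")
api_label_set <- function(api_class) {
  stopifnot(is.character(api_class), length(api_class) == 1L)
  m <- activity_scheme()$api
  if (!api_class %in% names(m)) {
    stop(sprintf("unknown recognizer class '%s'", api_class))
  }
  out <- m[[api_class]]
  if (is.null(out)) character(0) else as.character(out)
}

#' Recognizer class names
#'
#' @param evaluable If `TRUE`, drop classes whose mapped label set is empty
#'   (`TILTING`, `UNKNOWN`), which cannot be evaluated.
#' @return Character vector of class names.
#' @export
api_classes <- function(evaluable = FALSE) {
  m <- activity_scheme()$api
  cls <- names(m)
  if (evaluable) cls <- cls[vapply(m, length, 1L) > 0L]
  cls
}

#' MET intensity category bounds
#'
#' Standard category bounds on the Metabolic Equivalent of Task scale:
#' light (<= 2.99 METs), moderate (3.00-5.99), vigorous (6.00-8.99), with
#' MET = 6 as the conventional vigorous comparison line.
#'
#' @return Named numeric vector with elements `light_max`, `moderate_min`,
#'   `moderate_max`, `vigorous_min`, `vigorous_max`, `vigorous_line`.
#' @export
met_category_bounds <- function() {
  unlist(activity_scheme()$met_categories)
}

#' Categorize MET values into intensity bands
#'
#' Bounds are printed at 2-decimal precision, so inputs are rounded to 2
#' decimals before categorization; values above 8.99 are `out_of_range`.
#'
#' @param met Numeric vector of non-negative MET values.
#' @return Character vector in `{light, moderate, vigorous, out_of_range}`.
#' @export
#' @examples
#' met_category(c(2.99, 3.00, 5.99, 6.00, 9.5))
met_category <- function(met) {
  if (!is.numeric(met)) stop("met must be numeric")
  if (any(met < 0, na.rm = TRUE)) stop("met values must be non-negative")
  b <- met_category_bounds()
  m <- round(met, 2)
  out <- rep(NA_character_, length(m))
  out[m <= b[["light_max"]]] <- "light"
  out[m >= b[["moderate_min"]] & m <= b[["moderate_max"]]] <- "moderate"
  out[m >= b[["vigorous_min"]] & m <= b[["vigorous_max"]]] <- "vigorous"
  out[m > b[["vigorous_max"]]] <- "out_of_range"
  out
}
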