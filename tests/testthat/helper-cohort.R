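# Shared cohort bundles, memoized so multiple test files reuse them.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

small_cfg <- function(...) cohort_config(n_participants = 4, n_days = 2, ...)

default_bundle <- function() {
  cached("default_bundle", simulate_cohort(cohort_config(seed = 42)))
}

small_bundle <- function() {
  cached("small_bundle", simulate_cohort(small_cfg(seed = 42)))
}

quiet_pipeline <- function(bundle, ...) {
  suppressWarnings(run_pipeline(bundle$thigh_epochs, bundle$verbal$events,
                                bundle$wear_mask, ...))
}

# trimodal cadence sample with generating valleys at `valleys`
trimodal_cadence <- function(n, valleys = c(90, 130), sep = 18, sd = 7,
                             weights = c(0.45, 0.45, 0.10)) {
  means <- c(valleys[1] - sep, valleys[1] + sep, valleys[2] + sep)
  comp <- sample(1:3, n, replace = TRUE, prob = weights)
  stats::rnorm(n, means[comp], sd)
}
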