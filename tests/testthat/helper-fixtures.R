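# Fixture builders shared by the test files. All data are generated in code;
# nothing is read from disk.

# A minimal hand-built record table: counts per stage, two features.
# Stage-3 records get low feature values, stages 4/5 increasingly high ones,
# so tiny classification fixtures are (nearly) separable by construction.
toy_records <- function(n3 = 6, n4 = 3, n5 = 2, years = 2007:2015,
                        separable = TRUE, seed = 42) {
  withr::with_seed(seed, {
    stage <- rep(c(3L, 4L, 5L), c(n3, n4, n5))
    n <- length(stage)
    shift <- if (separable) (stage - 3L) * 3 else 0
    tibble::tibble(
      patient_id = sprintf("T%03d", seq_len(n)),
      visit_year = sample(years, n, replace = TRUE),
      stage = stage,
      f1 = rnorm(n) + shift,
      f2 = rnorm(n) - shift
    )
  })
}

# Small synthetic cohort shared by several model tests; generated once.
small_cohort_cfg <- function(seed = 11, ...) {
  cohort_config(
    n_patients = 120, n_condition_features = 30, k_sep45 = 8, k_sep5 = 4,
    seed = seed, ...
  )
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(small_cohort_cfg())
      cache <<- complete_case_filter(co$records)
    }
    cache
  }
})

# Reference-cohort config with a small feature space: the per-year stage
# counts are enforced regardless of the feature model, so count-level tests
# do not need the full 455 features.
reference_cfg_small <- function(seed = 1) {
  cohort_config(
    n_patients = 13111, n_condition_features = 12, k_sep45 = 4, k_sep5 = 2,
    seed = seed
  )
}

quick_spec <- function(seed = 1) base_spec(num_trees = 25, seed = seed)
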