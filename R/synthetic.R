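#' Configuration for the synthetic EHR cohort generator
#'
#' The generator emulates the documented structure of a longitudinal
#' primary-care CKD cohort: visit records of patients already at stage 3 or
#' higher, with a ~23:2:1 record-level imbalance across stages 3/4/5, a mean
#' of 17 visits per patient over the years 2007-2015, patient age centred at
#' 70 (SD 12), 60% female, sparse binary diagnosed-condition indicators, and
#' a 22.8% rate of records with at least one missing pertinent value.
#'
#' Class signal is planted in two places so that the two-level
#' classification task is learnable but imperfect: a set of `k_sep45`
#' condition indicators whose odds are multiplied by `odds_mult_45` for
#' stages 4-5 (separating advanced disease from stage 3), a further `k_sep5`
#' conditions with odds times `odds_mult_5` for stage 5 only (separating
#' stage 5 from stage 4), and vital signs shifted by `vital_shift`
#' within-class standard deviations for stages 4-5 plus `vital_shift_stage5`
#' more for stage 5.
#'
#' @param n_patients Number of patients. The default (1,200, about 20,000
#'   records) is the package's test-scale cohort; pass 13,111 for a
#'   full-scale cohort.
#' @param class_proportions Record-level target proportions for stages
#'   3/4/5; default 23/26, 2/26, 1/26.
#' @param visits_mean Mean visits per patient (visit count is
#'   1 + Poisson(`visits_mean` - 1)).
#' @param year_range Inclusive calendar-year range of visits.
#' @param n_condition_features,n_vital_features,n_demo_features Feature
#'   counts per category (defaults 447/4/4, i.e. 455 predictive features).
#' @param k_sep45,odds_mult_45 Number of condition indicators informative
#'   for stages 4-5 versus 3, and the odds multiplier applied to them.
#' @param k_sep5,odds_mult_5 Conditions informative for stage 5 versus 4,
#'   and their multiplier.
#' @param vital_shift,vital_shift_stage5 Vital-sign mean shifts in SD units.
#' @param missing_rate Probability that a record has at least one missing
#'   pertinent value.
#' @param include_excluded_features Also generate the 33 medication and 7
#'   CKD-indicator features (a 495-feature raw extract) so that
#'   [apply_feature_exclusions()] has something to remove.
#' @param seed Integer random seed; generation is fully reproducible.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 1200,
                          class_proportions = c(23, 2, 1) / 26,
                          visits_mean = 17,
                          year_range = c(2007L, 2015L),
                          n_condition_features = 447,
                          n_vital_features = 4,
                          n_demo_features = 4,
                          k_sep45 = 30, odds_mult_45 = 4,
                          k_sep5 = 15, odds_mult_5 = 3,
                          vital_shift = 0.8, vital_shift_stage5 = 0.5,
                          missing_rate = 0.228,
                          include_excluded_features = FALSE,
                          seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be at least 1.")
  if (length(class_proportions) != 3 || any(class_proportions <= 0)) {
    abort("`class_proportions` must be three positive values (stages 3, 4, 5).")
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("`class_proportions` must sum to 1.")
  }
  if (k_sep45 + k_sep5 > n_condition_features) {
    abort("`k_sep45` + `k_sep5` must not exceed `n_condition_features`.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      class_proportions = setNames(class_proportions, c("3", "4", "5")),
      visits_mean = visits_mean,
      year_range = as.integer(year_range),
      n_condition_features = as.integer(n_condition_features),
      n_vital_features = as.integer(n_vital_features),
      n_demo_features = as.integer(n_demo_features),
      k_sep45 = as.integer(k_sep45), odds_mult_45 = odds_mult_45,
      k_sep5 = as.integer(k_sep5), odds_mult_5 = odds_mult_5,
      vital_shift = vital_shift, vital_shift_stage5 = vital_shift_stage5,
      missing_rate = missing_rate,
      include_excluded_features = isTRUE(include_excluded_features),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %s patients, years %d-%d, %d+%d+%d features, seed %d\n",
    format(x$n_patients, big.mark = ","), x$year_range[1], x$year_range[2],
    x$n_demo_features, x$n_vital_features, x$n_condition_features, x$seed
  ))
  invisible(x)
}

schema_from_config <- function(cfg) {
  default_schema(
    n_conditions = cfg$n_condition_features,
    n_vitals = cfg$n_vital_features,
    n_demographics = cfg$n_demo_features,
    include_excluded = cfg$include_excluded_features
  )
}

# Apply an odds multiplier to a success probability.
odds_scale <- function(p, mult) mult * p / (1 - p + mult * p)

# Feature-model parameters shared by all records of one cohort: baseline
# condition prevalences (log-uniform on [0.001, 0.2], mimicking the long tail
# of rare diagnosis codes) and which conditions carry class signal.
draw_feature_params <- function(cfg) {
  nc <- cfg$n_condition_features
  prev <- exp(runif(nc, log(0.001), log(0.2)))
  list(
    prevalence = prev,
    idx_sep45 = seq_len(cfg$k_sep45),
    idx_sep5 = cfg$k_sep45 + seq_len(cfg$k_sep5),
    vital_mean = rep_len(c(75, 130, 78, 29), cfg$n_vital_features),
    vital_sd = rep_len(c(12, 18, 11, 6), cfg$n_vital_features)
  )
}

# Simulate feature columns for n records with given stages and per-record
# patient attributes. Returns a plain matrix, columns in schema order.
simulate_features <- function(cfg, params, stage, age, sex, race, ethnicity) {
  n <- length(stage)
  adv <- stage >= 4L
  st5 <- stage == 5L

  demo <- matrix(0, n, cfg$n_demo_features)
  base_demo <- cbind(age, sex, race, ethnicity)
  k <- min(4L, cfg$n_demo_features)
  demo[, seq_len(k)] <- base_demo[, seq_len(k), drop = FALSE]
  if (cfg$n_demo_features > 4L) {
    demo[, 5:cfg$n_demo_features] <- rnorm(n * (cfg$n_demo_features - 4L))
  }

  nv <- cfg$n_vital_features
  shift <- cfg$vital_shift * adv + cfg$vital_shift_stage5 * st5
  vitals <- matrix(rnorm(n * nv), n, nv)
  vitals <- sweep(vitals, 2, params$vital_sd, `*`)
  vitals <- sweep(vitals, 2, params$vital_mean, `+`)
  vitals <- vitals + outer(shift, params$vital_sd)

  nc <- cfg$n_condition_features
  p <- matrix(params$prevalence, n, nc, byrow = TRUE)
  if (length(params$idx_sep45) > 0 && any(adv)) {
    p[adv, params$idx_sep45] <-
      odds_scale(p[adv, params$idx_sep45, drop = FALSE], cfg$odds_mult_45)
  }
  if (length(params$idx_sep5) > 0 && any(st5)) {
    p[st5, params$idx_sep5] <-
      odds_scale(p[st5, params$idx_sep5, drop = FALSE], cfg$odds_mult_5)
  }
  conditions <- matrix(rbinom(n * nc, 1L, p), n, nc)

  out <- cbind(demo, vitals, conditions)
  if (cfg$include_excluded_features) {
    # CKD-indicator conditions: near-deterministic markers of the label,
    # which is exactly why they are excluded before modelling.
    ind_p <- cbind(
      0.05,                       # ckd_stage_2 (history)
      ifelse(stage == 3L, 0.7, 0.15),  # ckd_stage_3
      ifelse(stage == 4L, 0.7, 0.05),  # ckd_stage_4
      ifelse(st5, 0.5, 0.01),     # end_stage_renal_disease
      ifelse(adv, 0.4, 0.05),     # chronic_renal_failure
      ifelse(st5, 0.1, 0.005),    # history_of_renal_transplant
      ifelse(adv, 0.3, 0.02)      # renal_failure_syndrome
    )
    indicators <- matrix(rbinom(n * 7L, 1L, ind_p), n, 7L)
    med_base <- exp(runif(33, log(0.01), log(0.3)))
    mp <- matrix(med_base, n, 33, byrow = TRUE)
    mp[adv, ] <- odds_scale(mp[adv, , drop = FALSE], 3)
    medications <- matrix(rbinom(n * 33L, 1L, mp), n, 33)
    out <- cbind(out, indicators, medications)
  }
  out
}

# Blank out 1-3 pertinent feature values in a missing_rate fraction of rows.
inject_missing <- function(features, pertinent_idx, missing_rate) {
  n <- nrow(features)
  hit <- which(runif(n) < missing_rate)
  if (length(hit) == 0) return(features)
  n_miss <- sample.int(3L, length(hit), replace = TRUE)
  rows <- rep(hit, n_miss)
  cols <- sample(pertinent_idx, length(rows), replace = TRUE)
  features[cbind(rows, cols)] <- NA_real_
  features
}

#' Generate a synthetic imbalanced EHR cohort
#'
#' Simulates visit records according to a [cohort_config()]: per patient an
#' age drawn from Normal(70, 12) truncated to \[18, 100\], female sex with
#' probability 0.6, a categorical race/ethnicity code, a visit count of
#' 1 + Poisson(mean - 1), visit years uniform over the patient's active span
#' within the year range; per record a stage sampled from the configured
#' proportions and features drawn from the stage-conditional model described
#' in [cohort_config()]. A `missing_rate` fraction of records receives one
#' to three missing pertinent values. Identical config and seed give
#' identical output.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `records` (visit-record tibble) and `schema`
#'   (feature schema tibble).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 7))
#' class_counts(cohort$records)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  schema <- schema_from_config(config)
  withr::with_seed(config$seed, {
    params <- draw_feature_params(config)
    np <- config$n_patients
    age0 <- pmin(pmax(rnorm(np, 70, 12), 18), 100)
    sex <- rbinom(np, 1L, 0.6)                      # 1 = female
    race <- sample.int(4L, np, replace = TRUE, prob = c(.6, .25, .1, .05))
    ethnicity <- sample.int(2L, np, replace = TRUE, prob = c(.85, .15))
    n_visits <- 1L + rpois(np, config$visits_mean - 1)

    y0 <- config$year_range[1]; y1 <- config$year_range[2]
    span_a <- sample(y0:y1, np, replace = TRUE)
    span_b <- sample(y0:y1, np, replace = TRUE)
    first_year <- pmin(span_a, span_b)
    last_year <- pmax(span_a, span_b)

    pid <- rep(sprintf("P%05d", seq_len(np)), n_visits)
    p_of <- rep(seq_len(np), n_visits)
    n <- length(pid)
    year <- first_year[p_of] +
      floor(runif(n) * (last_year[p_of] - first_year[p_of] + 1L))
    stage <- sample(STAGES, n, replace = TRUE, prob = config$class_proportions)
    age <- pmin(age0[p_of] + (year - first_year[p_of]), 100)

    feats <- simulate_features(config, params, stage,
                               age, sex[p_of], race[p_of], ethnicity[p_of])
    colnames(feats) <- schema$feature
    pertinent <- match(exclude_features(schema)$feature, schema$feature)
    if (config$missing_rate > 0) {
      feats <- inject_missing(feats, pertinent, config$missing_rate)
    }
    records <- dplyr::bind_cols(
      tibble(patient_id = pid, visit_year = as.integer(year),
             stage = as.integer(stage)),
      as_tibble(feats)
    )
    list(records = records, schema = schema)
  })
}

#' Per-year stage distribution of the reference cohort
#'
#' The fixed per-year, per-stage complete-record counts that
#' [generate_reference_cohort()] reproduces: 93,218 complete records over
#' 2007-2015 with an overall 23:2:1 stage imbalance, the final year holding
#' 9,576 records. These counts define the cohort profile the generator
#' emulates and let year-window splitting logic be validated against fixed
#' numbers.
#'
#' @return A tibble with columns `visit_year`, `stage` and `n`.
#' @export
reference_year_counts <- function() {
  tidyr::crossing(visit_year = 2007:2015, stage = STAGES) |>
    dplyr::arrange(.data$stage, .data$visit_year) |>
    dplyr::mutate(n = c(
      # stage 3 by year 2007..2015
      617L, 2681L, 4801L, 7463L, 10982L, 13809L, 15799L, 17273L, 8419L,
      # stage 4
      73L, 324L, 519L, 675L, 946L, 1338L, 1477L, 1624L, 782L,
      # stage 5
      57L, 132L, 231L, 306L, 447L, 597L, 704L, 767L, 375L
    )) |>
    dplyr::arrange(.data$visit_year, .data$stage)
}

#' Generate the reference cohort with exact per-year stage counts
#'
#' Produces a synthetic cohort whose complete-record counts per calendar
#' year and stage equal [reference_year_counts()] exactly (counts are
#' enforced; feature values are still synthetic, drawn from the same
#' stage-conditional model as [generate_cohort()]). With
#' `include_incomplete = TRUE` an additional 27,521 records carrying at
#' least one missing pertinent value are appended (for a total of 120,739),
#' so that [complete_case_filter()] recovers exactly the 93,218 complete
#' records.
#'
#' @param config A [cohort_config()]; its `year_range` must be 2007-2015.
#'   Feature-space size is taken from the config — count checks do not
#'   depend on it, so a small `n_condition_features` keeps this fast.
#' @param include_incomplete Append the incomplete records?
#' @return A list with elements `records` and `schema`, as
#'   [generate_cohort()].
#' @export
generate_reference_cohort <- function(config = cohort_config(n_patients = 13111),
                                      include_incomplete = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (!identical(config$year_range, c(2007L, 2015L))) {
    abort("The reference cohort requires `year_range = c(2007, 2015)`.")
  }
  counts <- reference_year_counts()
  n_complete <- sum(counts$n)
  n_incomplete <- if (include_incomplete) 27521L else 0L
  schema <- schema_from_config(config)

  withr::with_seed(config$seed, {
    params <- draw_feature_params(config)
    year <- rep(counts$visit_year, counts$n)
    stage <- rep(counts$stage, counts$n)
    if (n_incomplete > 0) {
      # Spread incomplete records over year x stage proportionally to the
      # complete counts (largest remainder); they are dropped by filtering,
      # so only the total matters.
      quota <- counts$n * n_incomplete / n_complete
      base <- floor(quota)
      short <- n_incomplete - sum(base)
      extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
      base[extra] <- base[extra] + 1L
      year <- c(year, rep(counts$visit_year, base))
      stage <- c(stage, rep(counts$stage, base))
    }
    n <- length(year)
    np <- config$n_patients
    p_of <- sample.int(np, n, replace = TRUE)
    age0 <- pmin(pmax(rnorm(np, 70, 12), 18), 100)
    sex <- rbinom(np, 1L, 0.6)
    race <- sample.int(4L, np, replace = TRUE, prob = c(.6, .25, .1, .05))
    ethnicity <- sample.int(2L, np, replace = TRUE, prob = c(.85, .15))
    age <- pmin(age0[p_of] + (year - 2007L), 100)

    feats <- simulate_features(config, params, stage,
                               age, sex[p_of], race[p_of], ethnicity[p_of])
    colnames(feats) <- schema$feature
    if (n_incomplete > 0) {
      pertinent <- match(exclude_features(schema)$feature, schema$feature)
      idx <- n_complete + seq_len(n_incomplete)
      n_miss <- sample.int(3L, n_incomplete, replace = TRUE)
      rows <- rep(idx, n_miss)
      cols <- sample(pertinent, length(rows), replace = TRUE)
      feats[cbind(rows, cols)] <- NA_real_
    }
    records <- dplyr::bind_cols(
      tibble(patient_id = sprintf("P%05d", p_of),
             visit_year = as.integer(year), stage = as.integer(stage)),
      as_tibble(feats)
    )
    # Interleave rows so incomplete records are not a trailing block.
    records <- records[sample.int(n), ]
    list(records = records, schema = schema)
  })
}
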