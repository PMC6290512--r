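#' Feature schema for visit-record tables
#'
#' A feature schema describes the columns of a visit-record table beyond the
#' identifier columns (`patient_id`, `visit_year`, `stage`): one row per
#' feature, with its category and two exclusion flags. Features flagged as
#' medications are removed because prescriptions can indicate an already
#' diagnosed stage rather than predict it; features flagged as CKD indicators
#' are diagnosed-condition codes that state the class label outright.
#'
#' @param feature Character vector of unique feature names.
#' @param category Category per feature: `"demographics"`, `"vitals"` or
#'   `"condition"` (recycled if length 1).
#' @param is_medication,is_ckd_indicator Logical exclusion flags (recycled).
#'
#' @return A tibble with columns `feature`, `category`, `is_medication`,
#'   `is_ckd_indicator`.
#' @seealso [default_schema()], [apply_feature_exclusions()]
#' @export
feature_schema <- function(feature, category = "condition",
                           is_medication = FALSE, is_ckd_indicator = FALSE) {
  if (anyDuplicated(feature)) {
    abort("Feature names must be unique.")
  }
  out <- tibble(
    feature = as.character(feature),
    category = rep_len(as.character(category), length(feature)),
    is_medication = rep_len(as.logical(is_medication), length(feature)),
    is_ckd_indicator = rep_len(as.logical(is_ckd_indicator), length(feature))
  )
  bad <- setdiff(unique(out$category), c("demographics", "vitals", "condition"))
  if (length(bad) > 0) {
    abort(paste0("Unknown feature category: ", paste(bad, collapse = ", "), "."))
  }
  out
}

# The seven diagnosed-condition codes that directly indicate CKD and are
# excluded from the predictive feature set.
ckd_indicator_conditions <- function() {
  c(
    "ckd_stage_2", "ckd_stage_3", "ckd_stage_4",
    "end_stage_renal_disease", "chronic_renal_failure",
    "history_of_renal_transplant", "renal_failure_syndrome"
  )
}

#' Default visit-record feature schema
#'
#' Builds the schema used by the synthetic cohort generator: 4 demographic
#' features (age, sex, race, ethnicity), 4 vital signs (heart rate, systolic
#' and diastolic blood pressure, body-mass index) and a configurable number of
#' binary diagnosed-condition indicators. With `include_excluded = TRUE` the
#' schema additionally carries 33 medication features and the seven
#' CKD-indicator conditions, mirroring a raw EHR extract before feature
#' exclusion (495 features for the default sizes); after
#' [apply_feature_exclusions()] the default full schema reduces to 455
#' features.
#'
#' @param n_conditions Number of predictive diagnosed-condition features.
#' @param n_vitals,n_demographics Numbers of vital-sign and demographic
#'   features. Values beyond the four named ones get generic names.
#' @param include_excluded Include the medication and CKD-indicator features?
#' @param n_medications Number of medication features when included.
#'
#' @return A feature schema tibble (see [feature_schema()]).
#' @export
default_schema <- function(n_conditions = 447, n_vitals = 4,
                           n_demographics = 4, include_excluded = FALSE,
                           n_medications = 33) {
  demo_names <- c("age", "sex", "race", "ethnicity")
  vital_names <- c("heart_rate", "systolic_bp", "diastolic_bp", "bmi")
  name_seq <- function(base, named, n) {
    if (n <= length(named)) named[seq_len(n)]
    else c(named, sprintf("%s_%02d", base, seq_len(n - length(named))))
  }
  parts <- list(
    feature_schema(name_seq("demo", demo_names, n_demographics), "demographics"),
    feature_schema(name_seq("vital", vital_names, n_vitals), "vitals"),
    feature_schema(sprintf("condition_%03d", seq_len(n_conditions)), "condition")
  )
  if (include_excluded) {
    parts <- c(parts, list(
      feature_schema(ckd_indicator_conditions(), "condition",
                     is_ckd_indicator = TRUE),
      feature_schema(sprintf("medication_%02d", seq_len(n_medications)),
                     "condition", is_medication = TRUE)
    ))
  }
  dplyr::bind_rows(parts)
}

#' Drop excluded features from a schema
#'
#' @param schema A feature schema tibble.
#' @return The schema restricted to features with neither exclusion flag set.
#' @export
exclude_features <- function(schema) {
  dplyr::filter(schema, !.data$is_medication, !.data$is_ckd_indicator)
}

#' Remove medication and CKD-indicator features from a record table
#'
#' Drops every feature column flagged `is_medication` or `is_ckd_indicator`
#' in the schema. The number of records is unchanged; with no flagged
#' features the table is returned as-is.
#'
#' @param data A visit-record table.
#' @param schema The feature schema describing `data`'s feature columns.
#' @return The record table without the excluded feature columns.
#' @export
apply_feature_exclusions <- function(data, schema) {
  assert_record_table(data)
  keep <- exclude_features(schema)$feature
  drop <- setdiff(schema$feature, keep)
  data[, c(META_COLS, intersect(names(data), keep)), drop = FALSE] |>
    as_tibble()
}

#' Read or write a schema sidecar file
#'
#' The sidecar is a YAML file listing each feature's name, category and
#' exclusion flags, stored next to the record CSV.
#'
#' @param schema A feature schema tibble.
#' @param path File path of the sidecar.
#' @return `read_schema()` returns a schema tibble; `write_schema()`
#'   invisibly returns `path`.
#' @export
write_schema <- function(schema, path) {
  lst <- purrr::pmap(schema, function(feature, category, is_medication,
                                      is_ckd_indicator) {
    list(name = feature, category = category,
         is_medication = is_medication, is_ckd_indicator = is_ckd_indicator)
  })
  yaml::write_yaml(list(features = lst), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(paste0("Schema file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$features)) abort("Schema sidecar has no `features` entry.")
  feature_schema(
    feature = purrr::map_chr(raw$features, "name"),
    category = purrr::map_chr(raw$features, "category"),
    is_medication = purrr::map_lgl(raw$features, ~ isTRUE(.x$is_medication)),
    is_ckd_indicator = purrr::map_lgl(raw$features, ~ isTRUE(.x$is_ckd_indicator))
  )
}
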