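#' Read visit records from a delimited file
#'
#' Records are stored as comma-separated UTF-8 text with a mandatory header:
#' `patient_id`, `visit_year`, `stage`, then one column per schema feature in
#' schema order. Empty cells encode missing values and are read as `NA`;
#' no imputation is performed anywhere in the package (downstream modelling
#' uses complete cases only, see [complete_case_filter()]).
#'
#' @param path Path to the CSV file.
#' @param schema Optional feature schema; when supplied the file header must
#'   contain exactly the schema's features after the three identifier columns.
#' @return A tibble of visit records, row order preserved.
#' @seealso [write_records()], [read_schema()]
#' @export
read_records <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("Record file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(META_COLS, header)
  if (length(missing) > 0) {
    abort(paste0("Record file is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (!is.null(schema)) {
    file_feats <- setdiff(header, META_COLS)
    if (!identical(sort(file_feats), sort(schema$feature))) {
      abort(paste0(
        "Header does not match the schema: ",
        length(setdiff(schema$feature, file_feats)), " schema feature(s) absent, ",
        length(setdiff(file_feats, schema$feature)), " unexpected column(s)."
      ))
    }
  }
  feats <- setdiff(header, META_COLS)
  types <- do.call(readr::cols, c(
    list(patient_id = readr::col_character(),
         visit_year = readr::col_integer(),
         stage = readr::col_integer()),
    setNames(rep(list(readr::col_double()), length(feats)), feats)
  ))
  # readr warns before we turn parse problems into errors below
  data <- suppressWarnings(
    readr::read_csv(path, col_types = types, na = "", progress = FALSE)
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed record file: row ", probs$row[1] - 1L,
                 " (", probs$expected[1], " expected, got '",
                 probs$actual[1], "')."))
  }
  if (!is.null(schema)) {
    data <- data[, c(META_COLS, schema$feature)]
  }
  assert_record_table(data)
  data
}

#' Write visit records to a delimited file
#'
#' Inverse of [read_records()]: header is `patient_id`, `visit_year`,
#' `stage` then the feature columns; missing values are written as empty
#' cells. Output is deterministic, so write-then-read is the identity.
#'
#' @param data A visit-record table.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_records <- function(data, path) {
  assert_record_table(data)
  data <- data[, c(META_COLS, feature_cols(data))]
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Keep only complete records
#'
#' Removes every record with at least one missing value on a pertinent
#' feature. "Pertinent" means the retained (post-exclusion) feature set: when
#' a `schema` is supplied, only features that survive [exclude_features()]
#' are inspected; otherwise all feature columns present in `data` count.
#'
#' @param data A visit-record table.
#' @param schema Optional feature schema restricting which columns count as
#'   pertinent.
#' @return The record table with incomplete records removed, order preserved.
#' @export
complete_case_filter <- function(data, schema = NULL) {
  assert_record_table(data)
  cols <- feature_cols(data)
  if (!is.null(schema)) cols <- intersect(cols, exclude_features(schema)$feature)
  if (length(cols) == 0 || nrow(data) == 0) return(as_tibble(data))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  as_tibble(data[keep, , drop = FALSE])
}

#' Count records per stage
#'
#' @param data A visit-record table.
#' @return A tibble with one row per stage (3, 4, 5) and its record count;
#'   absent stages are reported as 0.
#' @export
class_counts <- function(data) {
  assert_record_table(data)
  tibble(stage = STAGES) |>
    dplyr::left_join(dplyr::count(data, .data$stage), by = "stage") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Split records into temporally earlier training and later test sets
#'
#' Training contains the records whose `visit_year` lies in
#' `[first_train_year, last_train_year]`; the test set contains exactly the
#' records from `test_year`. Records outside both ranges are dropped. The
#' test year must follow the training window, emulating prospective
#' prediction from historical records.
#'
#' @param data A visit-record table.
#' @param first_train_year,last_train_year Inclusive training-year range.
#' @param test_year Single test year, strictly after `last_train_year`.
#' @return A `temporal_split` object: a list with elements `train`, `test`,
#'   `train_years` and `test_year`.
#' @export
temporal_split <- function(data, first_train_year, last_train_year, test_year) {
  assert_record_table(data)
  if (first_train_year > last_train_year) {
    abort("`first_train_year` must not exceed `last_train_year`.")
  }
  if (last_train_year >= test_year) {
    abort("`test_year` must be strictly after `last_train_year`.")
  }
  train <- dplyr::filter(data, .data$visit_year >= first_train_year,
                         .data$visit_year <= last_train_year)
  test <- dplyr::filter(data, .data$visit_year == test_year)
  structure(
    list(
      train = train, test = test,
      train_years = c(as.integer(first_train_year), as.integer(last_train_year)),
      test_year = as.integer(test_year)
    ),
    class = "temporal_split"
  )
}

#' @export
print.temporal_split <- function(x, ...) {
  cat(sprintf(
    "<temporal_split> train %d-%d (%s records), test %d (%s records)\n",
    x$train_years[1], x$train_years[2], format(nrow(x$train), big.mark = ","),
    x$test_year, format(nrow(x$test), big.mark = ",")
  ))
  invisible(x)
}
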