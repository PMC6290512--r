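#' One-vs-rest confusion counts for a class of interest
#'
#' For stage i: TP counts stage-i records correctly assigned to stage i,
#' TN records of other stages not assigned to stage i, FP records of other
#' stages misassigned to stage i, and FN stage-i records assigned
#' elsewhere. The four counts always sum to the number of records.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param class The class of interest.
#' @return A one-row tibble with columns `class`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, class) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  pos_t <- truth == class
  pos_p <- predicted == class
  tibble(
    class = as.character(class),
    tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
    fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p)
  )
}

#' Derive specificity, sensitivity, precision and F-measure from counts
#'
#' Specificity = TN/(TN+FP), sensitivity (true positive rate, recall) =
#' TP/(TP+FN), precision (positive predictive value) = TP/(TP+FP), and
#' F-measure = 2 * precision * sensitivity / (precision + sensitivity).
#' A 0/0 denominator yields 0 with a warning — conservative, and it keeps
#' aggregates defined on degenerate inputs (e.g. an empty predicted class).
#'
#' @param counts A tibble with columns `tp`, `tn`, `fp`, `fn` (one or more
#'   rows, e.g. from [confusion_counts()]).
#' @return `counts` with columns `specificity`, `sensitivity`, `precision`,
#'   `f_measure` appended.
#' @export
compute_metrics <- function(counts) {
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warn(paste0("0/0 in ", what, "; reporting 0."))
    }
    ifelse(bad, 0, num / den)
  }
  out <- dplyr::mutate(
    as_tibble(counts),
    specificity = safe_div(.data$tn, .data$tn + .data$fp, "specificity"),
    sensitivity = safe_div(.data$tp, .data$tp + .data$fn, "sensitivity"),
    precision = safe_div(.data$tp, .data$tp + .data$fp, "precision")
  )
  ps <- out$precision + out$sensitivity
  out$f_measure <- ifelse(ps == 0, 0, 2 * out$precision * out$sensitivity / ps)
  out
}

#' Per-class evaluation metrics
#'
#' One-vs-rest counts and derived metrics for each stage, optionally also
#' for the combined stages-4-and-5 class (truth and prediction collapsed
#' before counting).
#'
#' @param truth,predicted Equal-length stage label vectors over \{3,4,5\}.
#' @param include_combined Add a row for the combined `"45"` class.
#' @return A tibble with one row per class: counts plus specificity,
#'   sensitivity, precision and F-measure.
#' @export
class_metrics <- function(truth, predicted, include_combined = FALSE) {
  rows <- purrr::map(STAGES, ~ confusion_counts(truth, predicted, .x))
  if (include_combined) {
    collapse <- function(x) ifelse(x %in% c(4L, 5L), COMBINED_TOKEN,
                                   as.character(x))
    rows <- c(rows, list(
      confusion_counts(collapse(truth), collapse(predicted), COMBINED_TOKEN)
    ))
  }
  compute_metrics(dplyr::bind_rows(rows))
}

#' Macro-average of per-class metrics
#'
#' Unweighted mean of each metric over the three stages. All three stages
#' must be present in the per-class table.
#'
#' @param per_class A [class_metrics()] tibble.
#' @return A one-row tibble with `class = "macro"` and the averaged
#'   metrics.
#' @export
macro_average <- function(per_class) {
  stages <- as.character(STAGES)
  if (!all(stages %in% per_class$class)) {
    abort("Macro average requires rows for all three stages.")
  }
  per_class |>
    dplyr::filter(.data$class %in% stages) |>
    dplyr::summarise(dplyr::across(
      c("specificity", "sensitivity", "precision", "f_measure"), mean
    )) |>
    dplyr::mutate(class = "macro", .before = 1)
}

#' Run the strategy-comparison experiment
#'
#' For each strategy and each of `repeats` repetitions, refits the model on
#' the training side of a temporal split with seed `base_seed + r` — so
#' every repeat re-draws the balanced majority partitioning and reseeds the
#' base classifiers — predicts the fixed test set, and computes per-class
#' and macro metrics. The test set never varies across repeats.
#'
#' @param split A [temporal_split()] with a non-empty test set.
#' @param strategies Character vector of strategy names (see
#'   [fit_strategy()]).
#' @param spec A [base_spec()].
#' @param repeats Number of repetitions per strategy.
#' @param base_seed Integer; repeat r uses seed `base_seed + r`.
#' @param ... Passed to [fit_strategy()] (e.g. `M`, `alpha`).
#' @return An `experiment_result` object with elements `metrics`
#'   (per-repeat, per-class tibble) and `summary` (mean and standard
#'   deviation across repeats; the deviation is reported only when
#'   `repeats >= 2`).
#' @export
run_comparison <- function(split, strategies = c("hier_mc", "baseline_oaa"),
                           spec = base_spec(), repeats = 1, base_seed = 1L,
                           ...) {
  stopifnot(inherits(split, "temporal_split"))
  if (nrow(split$test) == 0) abort("The test set is empty.")
  if (repeats < 1) abort("`repeats` must be at least 1.")
  truth <- split$test$stage
  metrics <- purrr::map_dfr(strategies, function(strategy) {
    purrr::map_dfr(seq_len(repeats), function(r) {
      seed <- base_seed + r
      sp <- spec
      sp$seed <- as.integer(seed)
      fit <- fit_strategy(split$train, strategy, spec = sp, seed = seed, ...)
      pred <- predict(fit, split$test)
      per_class <- class_metrics(truth, pred)
      dplyr::bind_rows(per_class, macro_average(per_class)) |>
        dplyr::mutate(strategy = strategy, rep = r, seed = seed, .before = 1)
    })
  })
  summary <- metrics |>
    dplyr::group_by(.data$strategy, .data$class) |>
    dplyr::summarise(dplyr::across(
      c("specificity", "sensitivity", "precision", "f_measure"),
      list(mean = mean, sd = ~ if (repeats >= 2) sd(.x) else NA_real_)
    ), .groups = "drop")
  structure(
    list(metrics = metrics, summary = summary, repeats = repeats,
         base_seed = as.integer(base_seed),
         train_years = split$train_years, test_year = split$test_year,
         n_train = nrow(split$train), n_test = nrow(split$test)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %d strategy(ies) x %d repeat(s); train %d-%d (n=%s), test %d (n=%s)\n",
    dplyr::n_distinct(x$metrics$strategy), x$repeats,
    x$train_years[1], x$train_years[2], format(x$n_train, big.mark = ","),
    x$test_year, format(x$n_test, big.mark = ",")
  ))
  print(glance(x))
  invisible(x)
}

#' @describeIn run_comparison Per-strategy, per-class summary (means and,
#'   for two or more repeats, standard deviations).
#' @param x An `experiment_result`.
#' @method tidy experiment_result
#' @export
tidy.experiment_result <- function(x, ...) {
  x$summary
}

#' @describeIn run_comparison One row per strategy: macro-averaged
#'   sensitivity, specificity and F-measure (mean across repeats).
#' @method glance experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  x$summary |>
    dplyr::filter(.data$class == "macro") |>
    dplyr::select("strategy", sensitivity = "sensitivity_mean",
                  specificity = "specificity_mean",
                  f_measure = "f_measure_mean",
                  sensitivity_sd = "sensitivity_sd")
}

#' @describeIn run_comparison Per-class sensitivity and F-measure by
#'   strategy, as grouped bars.
#' @param object An `experiment_result`.
#' @method autoplot experiment_result
#' @export
autoplot.experiment_result <- function(object, ...) {
  object$summary |>
    dplyr::filter(.data$class != "macro") |>
    dplyr::select("strategy", "class", Sensitivity = "sensitivity_mean",
                  `F-measure` = "f_measure_mean") |>
    tidyr::pivot_longer(c("Sensitivity", "F-measure"),
                        names_to = "metric") |>
    ggplot(aes(x = .data$class, y = .data$value, fill = .data$strategy)) +
    geom_col(position = "dodge") +
    facet_wrap(~metric) +
    labs(x = "CKD stage", y = NULL, fill = NULL) +
    ylim(0, 1) +
    theme_minimal()
}

#' Training-history truncation experiment
#'
#' Re-runs the comparison over progressively truncated training windows:
#' window i trains on years `first_years[i]` .. `last_train_year` while the
#' test year stays fixed, emulating prediction from shorter and more recent
#' patient history. Emits the per-window, per-stage true-positive-rate
#' table alongside the full metric tables.
#'
#' @param data A visit-record table covering the windows and the test year.
#' @param first_years Integer vector of window start years (each window
#'   ends at `last_train_year`).
#' @param last_train_year Final training year shared by all windows.
#' @param test_year Fixed test year, after `last_train_year`.
#' @param strategies,spec,repeats,base_seed,... As [run_comparison()].
#' @return A `truncation_result` object with elements `metrics`, `summary`
#'   (both carrying a `window` column) and `tpr` (per window and stage,
#'   mean sensitivity).
#' @export
run_truncation <- function(data, first_years = 2007:2014,
                           last_train_year = 2014, test_year = 2015,
                           strategies = "hier_mc", spec = base_spec(),
                           repeats = 1, base_seed = 1L, ...) {
  assert_record_table(data)
  if (length(first_years) == 0) abort("`first_years` is empty.")
  runs <- purrr::map(first_years, function(y0) {
    split <- temporal_split(data, y0, last_train_year, test_year)
    if (nrow(split$train) == 0) {
      abort(sprintf("Training window %d-%d is empty.", y0, last_train_year))
    }
    run_comparison(split, strategies = strategies, spec = spec,
                   repeats = repeats, base_seed = base_seed, ...)
  })
  label <- sprintf("%d-%d", first_years, last_train_year)
  metrics <- purrr::map2_dfr(runs, label, ~ dplyr::mutate(.x$metrics,
                                                          window = .y,
                                                          .before = 1))
  summary <- purrr::map2_dfr(runs, label, ~ dplyr::mutate(.x$summary,
                                                          window = .y,
                                                          .before = 1))
  tpr <- summary |>
    dplyr::filter(.data$class %in% as.character(STAGES)) |>
    dplyr::select("window", "strategy", stage = "class",
                  tpr = "sensitivity_mean")
  structure(
    list(metrics = metrics, summary = summary, tpr = tpr,
         first_years = as.integer(first_years),
         n_train = purrr::map_int(runs, "n_train"),
         test_year = as.integer(test_year)),
    class = "truncation_result"
  )
}

#' @export
print.truncation_result <- function(x, ...) {
  cat(sprintf("<truncation_result> %d training windows, test year %d\n",
              length(x$first_years), x$test_year))
  print(tidyr::pivot_wider(x$tpr, names_from = "stage", values_from = "tpr",
                           names_prefix = "stage_"))
  invisible(x)
}

#' @describeIn run_truncation Per-window summary table.
#' @param x A `truncation_result`.
#' @method tidy truncation_result
#' @export
tidy.truncation_result <- function(x, ...) {
  x$summary
}

#' @describeIn run_truncation True-positive rate per stage against the
#'   training window, as line plots.
#' @param object A `truncation_result`.
#' @method autoplot truncation_result
#' @export
autoplot.truncation_result <- function(object, ...) {
  object$tpr |>
    dplyr::mutate(window = factor(.data$window,
                                  levels = unique(.data$window))) |>
    ggplot(aes(x = .data$window, y = .data$tpr,
               colour = .data$stage, group = .data$stage)) +
    geom_line() +
    geom_point() +
    labs(x = "Training window", y = "True positive rate",
         colour = "CKD stage") +
    ylim(0, 1) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
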