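#' Fit the hierarchical meta-classifier
#'
#' Composes the two levels of the hierarchy: a coarse meta-classification
#' step ([fit_coarse()]) separating stage 3 from the combined stages 4-5,
#' and a refinement step ([fit_refinement()]) splitting the combined class
#' into its constituents. The training set must contain all three stages.
#' Fitting is deterministic given `seed` and `spec$seed`.
#'
#' @param data Training visit-record table with stages 3, 4 and 5.
#' @param spec A [base_spec()] shared by the base classifiers and the
#'   refinement classifier.
#' @param M Coarse ensemble size or `"auto"` ([n_partitions()] on the
#'   coarse counts).
#' @param seed Integer seed for the balanced partitioning.
#' @param alpha Laplace smoothing constant of the meta-classifier.
#' @param mode Balanced-subset construction mode, see
#'   [balanced_partitions()].
#' @param out_of_fold Use out-of-fold base labels for meta-training.
#' @param balance_refinement Apply balanced-subset machinery in the
#'   refinement step as well.
#' @return A `hier_mc` object (also a `stage_model`); `predict()` returns
#'   integer stages 3/4/5.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 60, seed = 3,
#'                                         n_condition_features = 20,
#'                                         k_sep45 = 8, k_sep5 = 4))
#' recs <- complete_case_filter(cohort$records)
#' split <- temporal_split(recs, 2007, 2014, 2015)
#' fit <- fit_hier_mc(split$train, base_spec(num_trees = 20), M = 2)
#' table(predict(fit, split$test), split$test$stage)
#' @export
fit_hier_mc <- function(data, spec = base_spec(), M = "auto", seed = 1L,
                        alpha = 1, mode = c("partition", "resample"),
                        out_of_fold = FALSE, balance_refinement = FALSE) {
  assert_record_table(data)
  mode <- match.arg(mode)
  if (!all(STAGES %in% data$stage)) {
    abort("Hierarchical meta-classifier training requires all three stages.")
  }
  coarse <- fit_coarse(data, spec = spec, M = M, seed = seed, alpha = alpha,
                       mode = mode, out_of_fold = out_of_fold)
  refine <- fit_refinement(data, spec = spec, balance = balance_refinement,
                           seed = seed)
  structure(
    list(
      coarse = coarse, refine = refine, spec = spec,
      schema_fingerprint = rlang::hash(feature_cols(data)),
      features = feature_cols(data),
      seeds = c(partition = as.integer(seed), base = spec$seed)
    ),
    class = c("hier_mc", "stage_model")
  )
}

#' @export
print.hier_mc <- function(x, ...) {
  cat(sprintf(
    "<hier_mc> coarse: %d %s base classifiers + naive-Bayes meta; refinement: %s\n",
    x$coarse$subsets_meta$M, x$spec$method, x$refine$spec$method
  ))
  invisible(x)
}

#' Predict stages with a hierarchical meta-classifier
#'
#' Applies the coarse step first; records labelled stage 3 are final, and
#' records assigned to the combined class are routed through the
#' refinement classifier, so every record ends with a label in
#' \{3, 4, 5\}.
#'
#' @param object A fitted [fit_hier_mc()] model.
#' @param newdata Visit-record table with the training feature columns.
#' @param ... Unused.
#' @return Integer vector of predicted stages.
#' @export
predict.hier_mc <- function(object, newdata, ...) {
  assert_record_table(newdata)
  if (!identical(rlang::hash(intersect(feature_cols(newdata), object$features)),
                 rlang::hash(object$features)) &&
      length(setdiff(object$features, feature_cols(newdata))) > 0) {
    abort("Feature columns do not match the model's training schema.")
  }
  coarse_lab <- predict(object$coarse, newdata)
  out <- rep(3L, nrow(newdata))
  combined <- which(coarse_lab == COMBINED_TOKEN)
  if (length(combined) > 0) {
    out[combined] <- predict(object$refine,
                             newdata[combined, , drop = FALSE])
  }
  out
}

#' SMOTE over-sampling of minority stages
#'
#' Augments the record table with synthetic minority records until every
#' stage reaches the majority stage's count, following the original SMOTE
#' definition: each synthetic record interpolates between a randomly chosen
#' minority record x and one of its k nearest minority-class neighbours x'
#' (Euclidean distance on the feature vector), at x + u (x' - x) with
#' u ~ Uniform(0, 1).
#'
#' @param data A complete-case visit-record table.
#' @param k Number of nearest neighbours (default 5, the original choice).
#' @param seed Integer seed.
#' @return The augmented record table; synthetic records carry
#'   `patient_id` `"synthetic_<stage>_<i>"` and the visit year of their
#'   base record.
#' @export
smote_augment <- function(data, k = 5, seed = 1L) {
  assert_record_table(data)
  counts <- class_counts(data)
  n_max <- max(counts$n)
  need <- dplyr::filter(counts, .data$n < n_max, .data$n > 0)
  if (nrow(need) == 0) return(as_tibble(data))
  small <- dplyr::filter(need, .data$n < k + 1)
  if (nrow(small) > 0) {
    abort(sprintf(
      "Stage %s has only %d records; SMOTE with k = %d needs at least %d. Use a smaller k.",
      small$stage[1], small$n[1], k, k + 1
    ))
  }
  fcols <- feature_cols(data)
  synth <- withr::with_seed(seed, purrr::pmap(need, function(stage, n) {
    cls <- data[data$stage == stage, , drop = FALSE]
    x <- as.matrix(cls[, fcols, drop = FALSE])
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    # k nearest same-class neighbours of each record
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    m <- n_max - n
    base <- sample.int(nrow(x), m, replace = TRUE)
    nbr <- nn[cbind(base, sample.int(k, m, replace = TRUE))]
    u <- runif(m)
    feats <- x[base, , drop = FALSE] +
      u * (x[nbr, , drop = FALSE] - x[base, , drop = FALSE])
    dplyr::bind_cols(
      tibble(patient_id = sprintf("synthetic_%d_%d", stage, seq_len(m)),
             visit_year = cls$visit_year[base], stage = as.integer(stage)),
      as_tibble(feats)
    )
  }))
  dplyr::bind_rows(as_tibble(data), synth)
}

# One plain multiclass classifier over the original features; the
# inherently binary logistic family uses one-against-all inside fit_base.
fit_multiclass <- function(data, spec, seed) {
  fit <- fit_base(feature_matrix(data), as.character(data$stage), spec, seed)
  structure(
    list(fit = fit, spec = spec, features = feature_cols(data)),
    class = c("multiclass_model", "stage_model")
  )
}

#' @export
predict.multiclass_model <- function(object, newdata, ...) {
  as.integer(predict_base(object$fit, feature_matrix(newdata)))
}

#' Fit a comparator strategy
#'
#' The comparison harness covers four alternatives to the hierarchical
#' meta-classifier, all exposing the same fit/predict contract:
#' * `baseline_oaa` — one plain classifier on the imbalanced training set,
#'   no imbalance handling (one-against-all decomposition for logistic
#'   regression, native multiclass otherwise);
#' * `under_sampling` — every stage randomly down-sampled without
#'   replacement to the smallest stage's count, then one classifier (set
#'   `undersample_all = FALSE` to down-sample only the majority stage to
#'   the second-largest count);
#' * `smote` — minority stages over-sampled to the majority size with
#'   [smote_augment()], then one classifier;
#' * `simple_mc` — the non-hierarchical meta-classifier
#'   ([fit_simple_mc()]).
#'
#' @param data Training visit-record table with all three stages.
#' @param strategy One of the four strategy names.
#' @param spec A [base_spec()].
#' @param seed Integer seed for sampling.
#' @param smote_k Neighbour count for SMOTE.
#' @param undersample_all Down-sample all stages to the minimum count
#'   (default) or only the majority stage.
#' @param M Ensemble size for `simple_mc`.
#' @return A fitted `stage_model`; `predict()` returns integer stages.
#' @export
fit_comparator <- function(data, strategy = c("baseline_oaa", "under_sampling",
                                              "smote", "simple_mc"),
                           spec = base_spec(), seed = 1L, smote_k = 5,
                           undersample_all = TRUE, M = "auto") {
  assert_record_table(data)
  strategy <- match.arg(strategy)
  if (length(unique(data$stage)) < 3) {
    abort("Comparator training requires all three stages.")
  }
  switch(
    strategy,
    baseline_oaa = fit_multiclass(data, spec, seed),
    under_sampling = {
      counts <- class_counts(data)
      target <- if (undersample_all) min(counts$n) else
        sort(counts$n, decreasing = TRUE)[2]
      sampled <- withr::with_seed(seed, {
        data |>
          dplyr::group_by(.data$stage) |>
          dplyr::slice_sample(n = target) |>  # capped at the group size
          dplyr::ungroup()
      })
      fit_multiclass(sampled, spec, seed)
    },
    smote = fit_multiclass(smote_augment(data, k = smote_k, seed = seed),
                           spec, seed),
    simple_mc = fit_simple_mc(data, spec = spec, M = M, seed = seed)
  )
}

#' Fit any stage-prediction strategy by name
#'
#' Uniform entry point used by the comparison harness: `"hier_mc"` fits
#' [fit_hier_mc()], the other names dispatch to [fit_comparator()].
#'
#' @inheritParams fit_comparator
#' @param strategy Strategy name.
#' @param ... Passed to the underlying fitting function.
#' @return A fitted `stage_model`.
#' @export
fit_strategy <- function(data, strategy, spec = base_spec(), seed = 1L, ...) {
  if (identical(strategy, "hier_mc")) {
    fit_hier_mc(data, spec = spec, seed = seed, ...)
  } else {
    fit_comparator(data, strategy = strategy, spec = spec, seed = seed, ...)
  }
}
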