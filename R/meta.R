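#' Re-represent records as vectors of base-classifier labels
#'
#' Applies each of the M fitted base classifiers to every record and stacks
#' the predicted labels into one M-column table: the k-th record becomes the
#' vector of labels assigned to it by models 1..M, in model order. This
#' label vector — not the original features — is the input representation
#' of the meta-classifier.
#'
#' @param models List of fitted base models from [train_base_classifiers()].
#' @param data A visit-record table with the training feature columns.
#' @return A tibble with character columns `base_1` .. `base_M`.
#' @export
build_meta_representation <- function(models, data) {
  assert_record_table(data)
  x <- feature_matrix(data)
  missing <- setdiff(models[[1]]$features, colnames(x))
  if (length(missing) > 0) {
    abort(paste0("Record table lacks ", length(missing),
                 " feature(s) the base classifiers were trained on."))
  }
  labs <- lapply(models, predict_base, x = x)
  names(labs) <- sprintf("base_%d", seq_along(models))
  as_tibble(labs)
}

#' Categorical naive-Bayes meta-classifier
#'
#' Fits a naive-Bayes classifier over the categorical label-vector
#' representation produced by [build_meta_representation()], from scratch:
#' class priors are empirical frequencies and each base classifier's label
#' is a categorical feature with Laplace-smoothed conditionals
#' `P(C_j = v | class) = (n_jv_c + alpha) / (n_c + alpha * |alphabet|)`.
#' Prediction compares `log prior + sum_j log conditional` across classes.
#'
#' @param meta Label-vector table (one character column per base classifier).
#' @param labels Character class label per record (e.g. `"3"` / `"45"`).
#' @param alpha Laplace smoothing constant, > 0 (default 1).
#' @param alphabet Possible base-classifier labels; defaults to the values
#'   observed in `meta`.
#' @param class_preference Order in which classes win posterior ties; the
#'   default puts the combined minority class first, so a tie is resolved
#'   toward the severe classes (a missed advanced-stage case costs more
#'   than a false alarm).
#' @return An `nb_meta` object with elements `priors`, `conditionals` (one
#'   class-by-alphabet probability matrix per base classifier), `alphabet`,
#'   `classes`, `alpha`.
#' @export
fit_naive_bayes_meta <- function(meta, labels, alpha = 1,
                                 alphabet = NULL,
                                 class_preference = NULL) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (alpha <= 0) abort("`alpha` must be positive.")
  if (nrow(meta) != length(labels)) {
    abort("`meta` and `labels` lengths differ.")
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort("Meta-training labels contain a single class; need at least two.")
  }
  alphabet <- alphabet %||% sort(unique(unlist(meta, use.names = FALSE)))
  class_preference <- class_preference %||%
    intersect(c(COMBINED_TOKEN, "5", "4", "3"), classes)
  n_c <- table(factor(labels, levels = classes))
  priors <- as.numeric(n_c) / length(labels)
  names(priors) <- classes
  conditionals <- lapply(meta, function(v) {
    v <- as.character(v)
    counts <- table(factor(labels, levels = classes),
                    factor(v, levels = alphabet))
    sm <- (unclass(counts) + alpha) /
      (as.numeric(n_c) + alpha * length(alphabet))
    sm
  })
  names(conditionals) <- names(meta)
  structure(
    list(priors = priors, conditionals = conditionals, alphabet = alphabet,
         classes = classes, alpha = alpha,
         class_preference = class_preference),
    class = "nb_meta"
  )
}

# Posterior log-score matrix (records x classes); NA label entries (used by
# the out-of-fold mode) simply drop that base classifier's term.
nb_meta_scores <- function(object, meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (ncol(meta) != length(object$conditionals)) {
    abort(sprintf("Label table has %d columns; model expects %d.",
                  ncol(meta), length(object$conditionals)))
  }
  n <- nrow(meta)
  scores <- matrix(log(object$priors), n, length(object$classes), byrow = TRUE)
  colnames(scores) <- object$classes
  for (j in seq_along(object$conditionals)) {
    v <- as.character(meta[[j]])
    idx <- match(v, object$alphabet)
    if (anyNA(idx) && !anyNA(v)) {
      abort(sprintf("Column %d contains labels outside the alphabet.", j))
    }
    lc <- log(object$conditionals[[j]])   # classes x alphabet
    contrib <- t(lc)[idx, , drop = FALSE] # records x classes
    contrib[is.na(idx), ] <- 0
    scores <- scores + contrib
  }
  scores
}

#' @describeIn fit_naive_bayes_meta Predict class labels for a label-vector
#'   table; posterior ties resolve by `class_preference` order.
#' @param object A fitted `nb_meta` model.
#' @param newdata Label-vector table to classify.
#' @param ... Unused.
#' @export
predict.nb_meta <- function(object, newdata, ...) {
  scores <- nb_meta_scores(object, newdata)
  pref <- match(object$class_preference, colnames(scores))
  ordered <- scores[, pref, drop = FALSE]
  object$class_preference[max.col(ordered, ties.method = "first")]
}

# Shared engine for both meta-classification steps: partition the majority
# class, train M base classifiers with labels collapsed through `label_map`,
# re-represent the full (imbalanced) training set, and fit the NB meta.
fit_meta_binary <- function(data, majority, minority, label_map, spec, M,
                            seed, alpha, mode, out_of_fold, class_preference) {
  subsets <- balanced_partitions(data, M = M, majority = majority,
                                 minority = minority, seed = seed, mode = mode)
  models <- train_base_classifiers(subsets, spec, label_map = label_map)
  meta <- build_meta_representation(models, data)
  if (out_of_fold) {
    # Blank the label a model assigns to records it was trained on; the NB
    # counts and posteriors skip those entries.
    key <- paste(data$patient_id, data$visit_year, data$stage)
    for (j in seq_len(subsets$M)) {
      sj <- subsets$subsets[[j]]
      seen <- key %in% paste(sj$patient_id, sj$visit_year, sj$stage)
      meta[[j]][seen] <- NA_character_
    }
  }
  labels <- unname(label_map[as.character(data$stage)])
  nb <- fit_naive_bayes_meta(
    meta, labels, alpha = alpha,
    alphabet = sort(unique(unname(label_map))),
    class_preference = class_preference
  )
  list(subsets_meta = subsets[c("M", "minority_size", "seed", "mode",
                                "n_unused_majority")],
       base_models = models, nb = nb)
}

#' Fit the coarse meta-classification step
#'
#' The first level of the hierarchy: separates the majority class (stage 3)
#' from the combined minority class (stages 4 and 5). The majority class is
#' partitioned into M balanced subsets ([balanced_partitions()]), one base
#' classifier is trained per subset ([train_base_classifiers()]), every
#' training record is re-represented as its M-vector of predicted labels,
#' and a categorical naive-Bayes meta-classifier
#' ([fit_naive_bayes_meta()]) is fitted on that representation.
#'
#' The meta-classifier is trained on the label vectors of the full
#' imbalanced training set, including records the base classifiers saw
#' during their own training; base labels on such records may be
#' optimistic. `out_of_fold = TRUE` instead blanks each model's label on
#' its own training records.
#'
#' @param data Training visit-record table containing stage 3 and at least
#'   one of stages 4/5.
#' @param spec A [base_spec()].
#' @param M Ensemble size, or `"auto"` for [n_partitions()] on the coarse
#'   class counts.
#' @param seed Integer seed for the majority-class partitioning.
#' @param alpha Laplace smoothing for the meta-classifier.
#' @param mode Subset construction mode, see [balanced_partitions()].
#' @param out_of_fold Use out-of-fold base labels for meta-training.
#' @return A `coarse_model` object.
#' @export
fit_coarse <- function(data, spec = base_spec(), M = "auto", seed = 1L,
                       alpha = 1, mode = c("partition", "resample"),
                       out_of_fold = FALSE) {
  assert_record_table(data)
  mode <- match.arg(mode)
  parts <- fit_meta_binary(
    data, majority = 3L, minority = c(4L, 5L),
    label_map = c("3" = "3", "4" = COMBINED_TOKEN, "5" = COMBINED_TOKEN),
    spec = spec, M = M, seed = seed, alpha = alpha, mode = mode,
    out_of_fold = out_of_fold,
    class_preference = c(COMBINED_TOKEN, "3")
  )
  structure(
    c(parts, list(spec = spec, seed = as.integer(seed),
                  features = feature_cols(data), out_of_fold = out_of_fold)),
    class = "coarse_model"
  )
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf(
    "<coarse_model> %d %s base classifiers + naive-Bayes meta (classes 3 / %s)\n",
    x$subsets_meta$M, x$spec$method, COMBINED_TOKEN
  ))
  invisible(x)
}

#' Coarse prediction: stage 3 versus the combined class
#'
#' @param object A fitted [fit_coarse()] model.
#' @param newdata Visit-record table to classify.
#' @param ... Unused.
#' @return Character vector of `"3"` / `"45"` labels.
#' @export
predict.coarse_model <- function(object, newdata, ...) {
  meta <- build_meta_representation(object$base_models, newdata)
  predict(object$nb, meta)
}

#' Fit the simple (non-hierarchical) meta-classifier
#'
#' Comparator using the same balanced-subset machinery as [fit_coarse()],
#' but the base classifiers keep the three original stage labels and the
#' naive-Bayes meta-classifier predicts directly among stages 3/4/5 from
#' the 3-valued label vectors. Posterior ties resolve toward the more
#' severe stage.
#'
#' @inheritParams fit_coarse
#' @return A `simple_mc_model` object; its `predict()` method returns
#'   integer stages.
#' @export
fit_simple_mc <- function(data, spec = base_spec(), M = "auto", seed = 1L,
                          alpha = 1, mode = c("partition", "resample")) {
  assert_record_table(data)
  mode <- match.arg(mode)
  if (length(unique(data$stage)) < 3) {
    abort("Simple meta-classifier training requires all three stages.")
  }
  parts <- fit_meta_binary(
    data, majority = 3L, minority = c(4L, 5L),
    label_map = c("3" = "3", "4" = "4", "5" = "5"),
    spec = spec, M = M, seed = seed, alpha = alpha, mode = mode,
    out_of_fold = FALSE,
    class_preference = c("5", "4", "3")
  )
  structure(
    c(parts, list(spec = spec, seed = as.integer(seed),
                  features = feature_cols(data))),
    class = c("simple_mc_model", "stage_model")
  )
}

#' @export
print.simple_mc_model <- function(x, ...) {
  cat(sprintf(
    "<simple_mc_model> %d %s base classifiers + 3-class naive-Bayes meta\n",
    x$subsets_meta$M, x$spec$method
  ))
  invisible(x)
}

#' @export
predict.simple_mc_model <- function(object, newdata, ...) {
  meta <- build_meta_representation(object$base_models, newdata)
  as.integer(predict(object$nb, meta))
}
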