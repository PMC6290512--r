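#' Base-classifier specification
#'
#' Describes the simple classifier family used for the ensemble's base
#' classifiers (and for the refinement and comparator models). Four common
#' families are supported; random forest is the default, as it performs
#' best both standalone and as an ensemble component in this setting.
#'
#' @param method One of `"random_forest"`, `"logistic_regression"`,
#'   `"naive_bayes"`, `"decision_tree"`.
#' @param num_trees Trees per random forest (default 100, unlimited depth).
#' @param seed Integer base seed; the j-th base classifier of an ensemble is
#'   seeded with `seed + j`.
#' @param ... Further hyperparameters passed to the underlying fitting
#'   function ([ranger::ranger()], [stats::glm()], [e1071::naiveBayes()] or
#'   [rpart::rpart()]).
#' @return A `base_spec` object.
#' @export
base_spec <- function(method = c("random_forest", "logistic_regression",
                                 "naive_bayes", "decision_tree"),
                      num_trees = 100, seed = 1L, ...) {
  method <- match.arg(method)
  structure(
    list(method = method, num_trees = num_trees, seed = as.integer(seed),
         extra = list(...)),
    class = "base_spec"
  )
}

#' @export
print.base_spec <- function(x, ...) {
  cat(sprintf("<base_spec> %s (seed %d%s)\n", x$method, x$seed,
              if (x$method == "random_forest")
                paste0(", ", x$num_trees, " trees") else ""))
  invisible(x)
}

# Fit one simple classifier on a feature matrix and factor labels.
# Multiclass logistic regression uses one-against-all binary models with an
# argmax over linear predictors; the other families are natively multiclass.
fit_base <- function(x, y, spec, seed) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    abort("Base-classifier training data contain a single class.")
  }
  fit <- withr::with_seed(seed, switch(
    spec$method,
    random_forest = ranger::ranger(
      x = x, y = y, num.trees = spec$num_trees,
      num.threads = 1, seed = seed
    ),
    logistic_regression = {
      lapply(setNames(levels(y), levels(y)), function(lv) {
        d <- data.frame(.y = as.integer(y == lv), x, check.names = FALSE)
        suppressWarnings(
          stats::glm(.y ~ ., data = d, family = stats::binomial())
        )
      })
    },
    naive_bayes = e1071::naiveBayes(x = x, y = y),
    decision_tree = rpart::rpart(
      .y ~ ., data = data.frame(.y = y, x, check.names = FALSE),
      method = "class"
    )
  ))
  structure(
    list(fit = fit, method = spec$method, levels = levels(y),
         features = colnames(x), seed = seed),
    class = "base_model"
  )
}

# Predicted labels (character) from a fitted base model.
predict_base <- function(model, x) {
  x <- x[, model$features, drop = FALSE]
  out <- switch(
    model$method,
    random_forest = as.character(
      # a fixed seed makes vote-tie breaking deterministic
      predict(model$fit, data = x, num.threads = 1,
              seed = model$seed)$predictions
    ),
    logistic_regression = {
      scores <- vapply(
        model$fit,
        function(m) predict(m, newdata = as.data.frame(x), type = "link"),
        numeric(nrow(x))
      )
      if (nrow(x) == 1) scores <- matrix(scores, nrow = 1)
      model$levels[max.col(scores, ties.method = "first")]
    },
    naive_bayes = as.character(predict(model$fit, newdata = x)),
    decision_tree = as.character(
      predict(model$fit, newdata = as.data.frame(x), type = "class")
    )
  )
  unname(out)
}

#' Train the M base classifiers of a coarse ensemble
#'
#' Fits one classifier per balanced subset, with the subset's stage labels
#' mapped through `label_map` (by default the coarse map sending stages 4
#' and 5 to the combined token `"45"`). The j-th model is seeded
#' `spec$seed + j`.
#'
#' @param subsets A [balanced_partitions()] result.
#' @param spec A [base_spec()].
#' @param label_map Named character vector mapping stage to training label.
#' @return A list of M fitted base models.
#' @export
train_base_classifiers <- function(subsets, spec = base_spec(),
                                   label_map = c("3" = "3", "4" = "45",
                                                 "5" = "45")) {
  stopifnot(inherits(subsets, "balanced_subsets"), inherits(spec, "base_spec"))
  lapply(seq_len(subsets$M), function(j) {
    d <- subsets$subsets[[j]]
    y <- unname(label_map[as.character(d$stage)])
    if (length(unique(y)) < 2) {
      abort(sprintf("Balanced subset %d contains a single class.", j))
    }
    fit_base(feature_matrix(d), y, spec, seed = spec$seed + j)
  })
}
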