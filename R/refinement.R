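#' Fit the refinement classifier (stage 4 versus stage 5)
#'
#' The second level of the hierarchy: a single two-class classifier trained
#' on the true stage-4/5 subset of the training records, under the original
#' feature representation. No re-balancing is applied between stages 4 and
#' 5 by default — their ~2:1 ratio is mild compared with the coarse
#' imbalance; `balance = TRUE` instead applies the same balanced-subset
#' meta-classification machinery with stage 4 as the majority.
#'
#' @param data Training visit-record table; must contain both stage 4 and
#'   stage 5 records (other stages are ignored).
#' @param spec A [base_spec()]; the classifier is seeded `spec$seed`.
#' @param balance Use balanced-subset meta-classification for 4 vs 5.
#' @param seed Seed for the subset draw when `balance = TRUE`.
#' @return A `refinement_model` object.
#' @export
fit_refinement <- function(data, spec = base_spec(), balance = FALSE,
                           seed = spec$seed) {
  assert_record_table(data)
  sub <- dplyr::filter(data, .data$stage %in% c(4L, 5L))
  n4 <- sum(sub$stage == 4L)
  n5 <- sum(sub$stage == 5L)
  if (n4 == 0 || n5 == 0) {
    abort("Refinement training requires both stage 4 and stage 5 records.")
  }
  if (balance) {
    maj <- if (n4 >= n5) 4L else 5L
    parts <- fit_meta_binary(
      sub, majority = maj, minority = setdiff(c(4L, 5L), maj),
      label_map = c("4" = "4", "5" = "5"),
      spec = spec, M = "auto", seed = seed, alpha = 1, mode = "partition",
      out_of_fold = FALSE, class_preference = c("5", "4")
    )
    fit <- parts
  } else {
    fit <- fit_base(feature_matrix(sub), as.character(sub$stage), spec,
                    seed = spec$seed)
  }
  structure(
    list(fit = fit, balance = balance, spec = spec,
         n_train = c("4" = n4, "5" = n5), features = feature_cols(data)),
    class = "refinement_model"
  )
}

#' @export
print.refinement_model <- function(x, ...) {
  cat(sprintf(
    "<refinement_model> %s%s on %d stage-4 + %d stage-5 records\n",
    x$spec$method, if (x$balance) " (balanced ensemble)" else "",
    x$n_train[["4"]], x$n_train[["5"]]
  ))
  invisible(x)
}

#' Refinement prediction: split combined-class records into stages 4 and 5
#'
#' Every input record receives stage 4 or stage 5; none remains under the
#' combined label.
#'
#' @param object A fitted [fit_refinement()] model.
#' @param newdata Visit-record table (typically the records the coarse step
#'   assigned to the combined class).
#' @param ... Unused.
#' @return Integer vector of 4/5 labels, one per input record.
#' @export
predict.refinement_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(integer(0))
  if (object$balance) {
    meta <- build_meta_representation(object$fit$base_models, newdata)
    as.integer(predict(object$fit$nb, meta))
  } else {
    as.integer(predict_base(object$fit, feature_matrix(newdata)))
  }
}
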