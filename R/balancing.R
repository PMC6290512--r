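#' Number of balanced majority-class partitions
#'
#' The ensemble size M equals the (floored) ratio of majority-class to
#' minority-class record counts, so that the majority class can be cut into
#' M subsets each as large as the whole minority class. At the reference
#' cohort's coarse imbalance (73,425 stage-3 records versus 10,217 records
#' of stages 4 and 5 combined) this gives M = 7.
#'
#' @param n_majority,n_minority Positive record counts; `n_majority` must be
#'   at least `n_minority`.
#' @return An integer M >= 1.
#' @export
n_partitions <- function(n_majority, n_minority) {
  if (n_minority <= 0) abort("Minority class has no records.")
  if (n_majority < n_minority) {
    abort("`n_majority` must be at least `n_minority`.")
  }
  max(1L, as.integer(n_majority %/% n_minority))
}

#' Build M balanced two-class training subsets
#'
#' Splits the majority class at random into M disjoint blocks of
#' `minority_size` records each (partition mode), and pairs every block with
#' the complete minority set, yielding M training sets with an exactly
#' uniform two-class distribution. Leftover majority records (when the
#' majority count is not a multiple of `M * minority_size`) are not used by
#' any subset. Each subset is shuffled before return.
#'
#' In `mode = "resample"` the M majority samples are instead drawn
#' independently (each without replacement), so blocks may overlap across
#' subsets.
#'
#' @param data A visit-record table containing both classes.
#' @param M Number of subsets; `"auto"` uses [n_partitions()] on the
#'   majority/minority counts.
#' @param majority Stage forming the majority class (default 3).
#' @param minority Stages forming the minority class (default 4 and 5,
#'   treated as one combined class).
#' @param seed Integer seed controlling the shuffling.
#' @param mode `"partition"` (disjoint blocks, the default) or
#'   `"resample"` (independent draws).
#' @return A `balanced_subsets` object: list with `subsets` (list of M
#'   record tibbles), `M`, `minority_size`, `seed`, `mode` and
#'   `n_unused_majority`.
#' @export
balanced_partitions <- function(data, M = "auto", majority = 3L,
                                minority = c(4L, 5L), seed = 1L,
                                mode = c("partition", "resample")) {
  assert_record_table(data)
  mode <- match.arg(mode)
  maj_idx <- which(data$stage == majority)
  min_idx <- which(data$stage %in% minority)
  n_maj <- length(maj_idx)
  n_min <- length(min_idx)
  if (n_min == 0) abort("Minority class has no records.")
  if (n_maj == 0) abort("Majority class has no records.")
  if (identical(M, "auto")) M <- n_partitions(n_maj, n_min)
  M <- as.integer(M)
  if (M < 1) abort("`M` must be at least 1.")
  if (mode == "partition" && n_maj < M * n_min) {
    abort(sprintf(
      "Majority class too small for %d disjoint blocks of %d: %d records available, %d needed (short by %d).",
      M, n_min, n_maj, M * n_min, M * n_min - n_maj
    ))
  }
  if (mode == "resample" && n_maj < n_min) {
    abort("Majority class smaller than the minority class.")
  }
  withr::with_seed(seed, {
    if (mode == "partition") {
      shuffled <- sample(maj_idx)
      blocks <- split(shuffled[seq_len(M * n_min)],
                      rep(seq_len(M), each = n_min))
    } else {
      blocks <- lapply(seq_len(M), function(j) sample(maj_idx, n_min))
    }
    subsets <- lapply(blocks, function(b) {
      idx <- c(b, min_idx)
      data[sample(idx), , drop = FALSE]
    })
  })
  structure(
    list(
      subsets = subsets, M = M, minority_size = n_min, seed = as.integer(seed),
      mode = mode, majority = majority, minority = minority,
      n_unused_majority = if (mode == "partition") n_maj - M * n_min else NA_integer_
    ),
    class = "balanced_subsets"
  )
}

#' @export
print.balanced_subsets <- function(x, ...) {
  cat(sprintf(
    "<balanced_subsets> M = %d subsets of %d records each (%d per class, mode %s)\n",
    x$M, 2L * x$minority_size, x$minority_size, x$mode
  ))
  if (!is.na(x$n_unused_majority) && x$n_unused_majority > 0) {
    cat(sprintf("  %d majority records unused by base-classifier training\n",
                x$n_unused_majority))
  }
  invisible(x)
}
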