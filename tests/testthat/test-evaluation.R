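# Brute-force confusion oracle: per-record loop, no vectorised sharing with
# the implementation.
oracle_confusion <- function(truth, pred, class) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == class && pred[i] == class) tp <- tp + 1
    else if (truth[i] != class && pred[i] != class) tn <- tn + 1
    else if (truth[i] != class && pred[i] == class) fp <- fp + 1
    else fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

test_that("confusion counts match hand examples and sum to n", {
  cc <- confusion_counts(c(3, 4, 5), c(3, 4, 5), 4)
  expect_equal(unlist(cc[, c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 2L, fp = 0L, fn = 0L))
  cc2 <- confusion_counts(c(4, 4), c(3, 5), 4)
  expect_equal(unlist(cc2[, c("tp", "tn", "fp", "fn")]),
               c(tp = 0L, tn = 0L, fp = 0L, fn = 2L))
  expect_error(confusion_counts(c(3, 4), c(3), 3), "equal length")
})

test_that("confusion counts agree with a brute-force tally on random labels", {
  withr::with_seed(17, {
    truth <- sample(c(3L, 4L, 5L), 1000, TRUE, prob = c(0.7, 0.2, 0.1))
    pred <- sample(c(3L, 4L, 5L), 1000, TRUE, prob = c(0.6, 0.25, 0.15))
  })
  for (cl in c(3L, 4L, 5L)) {
    got <- confusion_counts(truth, pred, cl)
    want <- oracle_confusion(truth, pred, cl)
    expect_equal(unlist(got[, c("tp", "tn", "fp", "fn")]), want)
    expect_equal(sum(want), 1000)
    # per-class identities: TP + FN = class count, TP + FP = predicted count
    expect_equal(got$tp + got$fn, sum(truth == cl))
    expect_equal(got$tp + got$fp, sum(pred == cl))
  }
  # micro consistency: summed TP over classes = correctly classified records
  tps <- sum(vapply(c(3L, 4L, 5L),
                    function(cl) confusion_counts(truth, pred, cl)$tp,
                    integer(1)))
  expect_equal(tps, sum(truth == pred))
})

test_that("metric formulas reproduce the printed precision example", {
  # 1,085 records predicted positive, 829 of them correct
  m <- compute_metrics(tibble::tibble(tp = 829, tn = 0, fp = 1085 - 829,
                                      fn = 0))
  expect_equal(m$precision, 829 / 1085, tolerance = 1e-12)
  expect_equal(round(m$precision, 2), 0.76)
})

test_that("metric edge cases behave as defined", {
  # TP = FN -> sensitivity one half; precision = sensitivity -> F equals both
  m <- compute_metrics(tibble::tibble(tp = 5, tn = 3, fp = 5, fn = 5))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$f_measure, 0.5)
  # zero numerator (nothing predicted positive also makes precision 0/0)
  m2 <- suppressWarnings(
    compute_metrics(tibble::tibble(tp = 0, tn = 10, fp = 0, fn = 5))
  )
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$f_measure, 0)
  # 0/0 denominators yield 0 with a warning
  expect_warning(
    m3 <- compute_metrics(tibble::tibble(tp = 0, tn = 10, fp = 0, fn = 0)),
    "0/0"
  )
  expect_equal(m3$precision, 0)
  expect_true(all(dplyr::select(m3, specificity:f_measure) >= 0 &
                    dplyr::select(m3, specificity:f_measure) <= 1))
})

test_that("macro average is the unweighted mean over the three stages", {
  withr::with_seed(23, {
    truth <- sample(c(3L, 4L, 5L), 300, TRUE, prob = c(0.7, 0.2, 0.1))
    pred <- sample(c(3L, 4L, 5L), 300, TRUE)
  })
  per_class <- class_metrics(truth, pred)
  macro <- macro_average(per_class)
  for (metric in c("specificity", "sensitivity", "precision", "f_measure")) {
    expect_equal(macro[[metric]], mean(per_class[[metric]]))
  }
  # constancy and a simple arithmetic case
  const <- tibble::tibble(class = c("3", "4", "5"), specificity = 0.7,
                          sensitivity = 0.7, precision = 0.7, f_measure = 0.7)
  expect_equal(macro_average(const)$sensitivity, 0.7)
  three <- dplyr::mutate(const, sensitivity = c(1, 0.5, 0))
  expect_equal(macro_average(three)$sensitivity, 0.5)
  expect_error(macro_average(const[1:2, ]), "three stages")
})

test_that("the combined-class row collapses stages 4 and 5 before counting", {
  truth <- c(3, 4, 5, 5, 3)
  pred <- c(3, 5, 4, 3, 4)
  pc <- class_metrics(truth, pred, include_combined = TRUE)
  comb <- dplyr::filter(pc, class == "45")
  # swapped 4/5 predictions are correct for the combined class
  expect_equal(comb$tp, 2L)
  expect_equal(comb$fn, 1L)
  expect_equal(comb$fp, 1L)
})

test_that("run_comparison aggregates per-repeat metrics with a fixed test set", {
  recs <- small_cohort()
  sp <- temporal_split(recs, 2007, 2014, 2015)
  # tiny test years can leave a stage unpredicted -> documented 0/0 warning
  res <- suppressWarnings(
    run_comparison(sp, c("baseline_oaa", "hier_mc"), quick_spec(),
                   repeats = 2, base_seed = 1, M = 2)
  )
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$metrics), 2 * 2 * 4)  # strategies x repeats x classes
  expect_setequal(unique(res$metrics$class), c("3", "4", "5", "macro"))
  expect_equal(unique(res$metrics$seed), c(2, 3))
  s <- tidy(res)
  expect_true(all(!is.na(s$sensitivity_sd)))
  g <- glance(res)
  expect_equal(nrow(g), 2)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("a single repeat reports no standard deviation", {
  recs <- small_cohort()
  sp <- temporal_split(recs, 2007, 2014, 2015)
  res <- suppressWarnings(
    run_comparison(sp, "baseline_oaa", quick_spec(), repeats = 1)
  )
  expect_true(all(is.na(tidy(res)$sensitivity_sd)))
})

test_that("identical seeds make repeats degenerate to zero variance", {
  recs <- small_cohort()
  sp <- temporal_split(recs, 2007, 2014, 2015)
  # same seed twice: refit is deterministic, so across-repeat sd must be 0
  r1 <- suppressWarnings(
    run_comparison(sp, "hier_mc", quick_spec(), repeats = 1,
                   base_seed = 5, M = 2)
  )
  r2 <- suppressWarnings(
    run_comparison(sp, "hier_mc", quick_spec(), repeats = 1,
                   base_seed = 5, M = 2)
  )
  expect_equal(r1$metrics$sensitivity, r2$metrics$sensitivity)
})

test_that("truncation experiment runs one comparison per window", {
  recs <- small_cohort()
  res <- suppressWarnings(
    run_truncation(recs, first_years = c(2007, 2012),
                   strategies = "baseline_oaa", spec = quick_spec(),
                   repeats = 1)
  )
  expect_s3_class(res, "truncation_result")
  expect_equal(unique(res$tpr$window), c("2007-2014", "2012-2014"))
  # one TPR row per stage per window
  expect_equal(nrow(res$tpr), 2 * 3)
  expect_s3_class(autoplot(res), "ggplot")
  # a single full-range window reproduces run_comparison
  sp <- temporal_split(recs, 2007, 2014, 2015)
  direct <- suppressWarnings(
    run_comparison(sp, "baseline_oaa", quick_spec(), repeats = 1,
                   base_seed = 1)
  )
  one <- suppressWarnings(
    run_truncation(recs, first_years = 2007,
                   strategies = "baseline_oaa", spec = quick_spec(),
                   repeats = 1, base_seed = 1)
  )
  expect_equal(one$metrics$sensitivity, direct$metrics$sensitivity)
  expect_error(run_truncation(recs, first_years = integer(0)), "empty")
})
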