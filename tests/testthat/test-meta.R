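# Independent naive-Bayes oracle: smoothed tables by explicit tallying and
# posteriors by direct products over every class, without any log/matrix
# machinery shared with the implementation.
oracle_nb_tables <- function(meta, labels, alpha, alphabet) {
  classes <- sort(unique(labels))
  lapply(seq_along(meta), function(j) {
    tab <- matrix(0, length(classes), length(alphabet),
                  dimnames = list(classes, alphabet))
    for (c in classes) {
      for (v in alphabet) {
        n_cv <- sum(labels == c & meta[[j]] == v)
        tab[c, v] <- (n_cv + alpha) / (sum(labels == c) + alpha * length(alphabet))
      }
    }
    tab
  })
}

oracle_nb_predict <- function(vec, priors, tables, tie_order) {
  post <- sapply(names(priors), function(c) {
    p <- priors[[c]]
    for (j in seq_along(vec)) p <- p * tables[[j]][c, vec[j]]
    p
  })
  best <- names(priors)[post == max(post)]
  tie_order[tie_order %in% best][1]
}

test_that("meta representation stacks base labels in model order", {
  recs <- toy_records(n3 = 20, n4 = 6, n5 = 4)
  bs <- balanced_partitions(recs, M = 2, seed = 1)
  models <- train_base_classifiers(bs, quick_spec())
  meta <- build_meta_representation(models, recs)
  expect_equal(dim(meta), c(nrow(recs), 2))
  expect_named(meta, c("base_1", "base_2"))
  expect_true(all(unlist(meta) %in% c("3", "45")))
  # pure function of (models, records)
  expect_equal(build_meta_representation(models, recs), meta)
  # column j is model j's prediction
  expect_equal(meta$base_2,
               hiermc:::predict_base(models[[2]],
                                     as.matrix(recs[, c("f1", "f2")])))
})

test_that("Laplace smoothing matches the hand-computed two-record example", {
  meta <- tibble::tibble(base_1 = c("3", "45"))
  fit <- fit_naive_bayes_meta(meta, labels = c("3", "45"), alpha = 1,
                              alphabet = c("3", "45"))
  # P(C_1 = 3 | class 3) = (1 + 1) / (1 + 2)
  expect_equal(fit$conditionals$base_1["3", "3"], 2 / 3)
  expect_equal(fit$conditionals$base_1["3", "45"], 1 / 3)
  expect_equal(unname(fit$priors), c(0.5, 0.5))
  # every conditional row sums to 1
  expect_equal(unname(rowSums(fit$conditionals$base_1)), c(1, 1))
})

test_that("fitted frequencies match brute-force counting on 200 records", {
  withr::with_seed(31, {
    meta <- tibble::tibble(
      base_1 = sample(c("3", "45"), 200, TRUE),
      base_2 = sample(c("3", "45"), 200, TRUE, prob = c(0.8, 0.2)),
      base_3 = sample(c("3", "45"), 200, TRUE)
    )
    labels <- sample(c("3", "45"), 200, TRUE, prob = c(0.7, 0.3))
  })
  fit <- fit_naive_bayes_meta(meta, labels, alpha = 1,
                              alphabet = c("3", "45"))
  oracle <- oracle_nb_tables(meta, labels, 1, c("3", "45"))
  for (j in 1:3) {
    expect_equal(unclass(fit$conditionals[[j]]), oracle[[j]],
                 ignore_attr = TRUE)
    expect_equal(unname(rowSums(fit$conditionals[[j]])), c(1, 1))
  }
  expect_equal(unname(fit$priors),
               c(mean(labels == "3"), mean(labels == "45")))
})

test_that("predictions match exhaustive posterior enumeration for M <= 4", {
  for (M in 2:4) {
    withr::with_seed(100 + M, {
      n <- 120
      meta <- tibble::as_tibble(setNames(
        replicate(M, sample(c("3", "45"), n, TRUE), simplify = FALSE),
        sprintf("base_%d", 1:M)
      ))
      labels <- ifelse(meta$base_1 == "45" | runif(n) < 0.2, "45", "3")
    })
    fit <- fit_naive_bayes_meta(meta, labels, alpha = 1,
                                alphabet = c("3", "45"))
    grid <- expand.grid(rep(list(c("3", "45")), M), stringsAsFactors = FALSE)
    names(grid) <- names(meta)
    got <- predict(fit, grid)
    want <- apply(grid, 1, oracle_nb_predict, priors = fit$priors,
                  tables = fit$conditionals, tie_order = c("45", "3"))
    expect_equal(got, unname(want))
  }
})

test_that("exact posterior ties resolve toward the combined minority class", {
  # symmetric construction: equal priors, complementary conditionals
  meta <- tibble::tibble(base_1 = c("3", "45", "3", "45"))
  labels <- c("3", "3", "45", "45")
  fit <- fit_naive_bayes_meta(meta, labels, alpha = 1, alphabet = c("3", "45"))
  # both conditionals are 1/2 everywhere -> posteriors equal for any input
  expect_true(all(fit$conditionals$base_1 == 0.5))
  expect_equal(predict(fit, tibble::tibble(base_1 = c("3", "45"))),
               c("45", "45"))
})

test_that("posterior is invariant to reordering base classifiers", {
  withr::with_seed(7, {
    meta <- tibble::as_tibble(setNames(
      replicate(3, sample(c("3", "45"), 80, TRUE), simplify = FALSE),
      c("base_1", "base_2", "base_3")
    ))
    labels <- sample(c("3", "45"), 80, TRUE)
  })
  fit <- fit_naive_bayes_meta(meta, labels, alphabet = c("3", "45"))
  perm <- c(3, 1, 2)
  fit_perm <- fit_naive_bayes_meta(meta[, perm], labels,
                                   alphabet = c("3", "45"))
  new <- meta[sample(80, 20), ]
  expect_equal(predict(fit_perm, new[, perm]), predict(fit, new))
})

test_that("degenerate and invalid meta-training inputs error", {
  meta <- tibble::tibble(base_1 = c("3", "3"))
  expect_error(fit_naive_bayes_meta(meta, c("3", "3")), "single class")
  expect_error(fit_naive_bayes_meta(meta, c("3", "45"), alpha = 0),
               "positive")
  fit <- fit_naive_bayes_meta(meta, c("3", "45"), alphabet = c("3", "45"))
  expect_error(predict(fit, tibble::tibble(a = "3", b = "45")), "columns")
})

test_that("training an ensemble yields one seeded model per subset", {
  recs <- toy_records(n3 = 40, n4 = 8, n5 = 4, seed = 5)
  bs <- balanced_partitions(recs, M = 3, seed = 2)
  models <- train_base_classifiers(bs, quick_spec(seed = 10))
  expect_length(models, 3)
  expect_equal(vapply(models, function(m) m$seed, numeric(1)), 11:13)
  expect_true(all(vapply(models, function(m)
    setequal(m$levels, c("3", "45")), logical(1))))
  # a training-set-separable subset is classified perfectly by its model
  x <- as.matrix(bs$subsets[[1]][, c("f1", "f2")])
  y <- ifelse(bs$subsets[[1]]$stage == 3, "3", "45")
  expect_gte(mean(hiermc:::predict_base(models[[1]], x) == y), 0.95)
})

test_that("with M = 1 the coarse step follows its single base classifier", {
  recs <- toy_records(n3 = 12, n4 = 6, n5 = 6, seed = 8)
  fit <- fit_coarse(recs, quick_spec(), M = 1, seed = 1)
  pred <- predict(fit, recs)
  base_lab <- hiermc:::predict_base(fit$base_models[[1]],
                                    as.matrix(recs[, c("f1", "f2")]))
  # on this separable fixture the meta posterior never inverts the base label
  expect_equal(pred, base_lab)
})

test_that("constant base predictions give constant meta vectors", {
  recs <- toy_records(n3 = 40, n4 = 6, n5 = 4, separable = FALSE, seed = 3)
  sep <- toy_records(n3 = 40, n4 = 6, n5 = 4, seed = 3)
  bs <- balanced_partitions(sep, M = 2, seed = 1)
  models <- train_base_classifiers(bs, quick_spec())
  shifted <- dplyr::mutate(recs, f1 = f1 + 200, f2 = f2 - 200)
  meta <- build_meta_representation(models, shifted)
  expect_true(all(meta$base_1 == meta$base_1[1]))
  expect_true(all(meta$base_2 == meta$base_2[1]))
})
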