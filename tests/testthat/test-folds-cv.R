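test_that("stratified folds balance classes and are seed-deterministic", {
  labels <- rep(c(1L, -1L), each = 5)
  f <- make_folds(labels, 5, seed = 3)
  for (k in 1:5) {
    expect_identical(sum(f$fold == k & labels == 1L), 1L)
    expect_identical(sum(f$fold == k & labels == -1L), 1L)
  }
  expect_identical(make_folds(labels, 5, seed = 3)$fold, f$fold)
  expect_false(identical(make_folds(labels, 5, seed = 4)$fold, f$fold))

  # uneven split: per-fold class counts within 1 of proportionality
  labels2 <- rep(c(1L, -1L), c(7, 11))
  f2 <- make_folds(labels2, 3, seed = 1)
  pos_per_fold <- table(f2$fold[labels2 == 1L])
  expect_true(all(pos_per_fold %in% c(2L, 3L)))
  expect_true(all(table(f2$fold) > 0))
  expect_length(f2$fold, 18L)
})

test_that("jackknife assigns one sample per fold in dataset order", {
  f <- make_folds(rep(c(1L, -1L), 2), "jackknife")
  expect_identical(f$fold, 1:4)
  expect_identical(f$K, 4L)
})

test_that("invalid fold requests are rejected", {
  labels <- rep(c(1L, -1L), each = 4)
  expect_error(make_folds(labels, 1), "K must be")
  expect_error(make_folds(labels, 9), "K must be")
  expect_error(make_folds(labels, 5), "requires >= 5")
})

test_that("fold making does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_folds(rep(c(1L, -1L), each = 10), 5, seed = 7))
  expect_identical(runif(1), before)
})

test_that("pooled CV reaches perfect accuracy on strongly separated classes", {
  b <- separable_benchmark(n = 10, L = 80)
  idx <- builtin_properties("DNA")
  folds <- make_folds(b$dataset$labels, 5, seed = 2)
  rep <- cross_validate(b$dataset, pse_params(2, 2, 0.5),
                        svm_params(4, 0.5), folds, idx)
  expect_equal(rep$acc, 1.0)
  expect_equal(rep$auc, 1.0)
  expect_identical(unname(rep$counts), c(10L, 0L, 10L, 0L))
})

test_that("jackknife equals K-fold at K = N and is fold-order independent", {
  b <- separable_benchmark(n = 6, L = 40, seed = 13)
  idx <- builtin_properties("DNA")
  pp <- pse_params(2, 1, 0.5)
  sp <- svm_params(1, 0.5)
  jack <- cross_validate(b$dataset, pp, sp,
                         make_folds(b$dataset$labels, "jackknife"), idx)
  kn <- cross_validate(b$dataset, pp, sp,
                       make_folds(b$dataset$labels, 12, seed = 5), idx)
  expect_identical(jack$scores, kn$scores)
  expect_identical(jack$pred, kn$pred)

  # renumbering folds (= evaluating them in another order) changes nothing
  folds <- make_folds(b$dataset$labels, 4, seed = 8)
  shuffled <- folds
  relabel <- c(3L, 1L, 4L, 2L)
  shuffled$fold <- relabel[folds$fold]
  r1 <- cross_validate(b$dataset, pp, sp, folds, idx)
  r2 <- cross_validate(b$dataset, pp, sp, shuffled, idx)
  expect_identical(r1$scores, r2$scores)
  expect_equal(r1$acc, r2$acc)
  expect_equal(r1$auc, r2$auc)
})

test_that("a training split losing a class is reported with its fold", {
  b <- separable_benchmark(n = 3, L = 30)
  folds <- make_folds(b$dataset$labels, 2, seed = 1)
  # force every positive into fold 1's test split
  folds$fold <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_error(cross_validate(b$dataset, pse_params(2, 1, 0.5),
                              svm_params(1, 1), folds,
                              builtin_properties("DNA")),
               "fold 1 lost a class")
})
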