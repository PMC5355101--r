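test_that("confusion metrics reproduce closed-form worked cases", {
  perfect <- compute_metrics(rep(c(1, -1), each = 5), rep(c(1, -1), each = 5))
  expect_identical(unname(perfect$counts), c(5L, 0L, 5L, 0L))
  expect_equal(c(perfect$acc, perfect$sn, perfect$sp, perfect$mcc),
               c(1, 1, 1, 1))

  # TP=3 TN=2 FP=2 FN=3: numerator 6-6 = 0, so MCC = 0 and Acc = 0.5
  truth <- c(rep(1, 6), rep(-1, 4))
  pred <- c(rep(1, 3), rep(-1, 3), rep(1, 2), rep(-1, 2))
  m <- compute_metrics(truth, pred)
  expect_identical(unname(m$counts), c(3L, 2L, 2L, 3L))
  expect_equal(m$mcc, 0)
  expect_equal(m$acc, 0.5)

  # all predicted positive: Sp = 0 and a zero denominator factor gives MCC 0
  m2 <- compute_metrics(c(1, 1, -1), c(1, 1, 1))
  expect_equal(m2$sp, 0)
  expect_equal(m2$mcc, 0)

  expect_error(compute_metrics(c(1, -1), c(1)), "lengths differ")
})

test_that("MCC stays in [-1,1] and sign-flips with inverted predictions", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    truth <- sample(c(1L, -1L), n, replace = TRUE)
    pred <- sample(c(1L, -1L), n, replace = TRUE)
    m <- compute_metrics(truth, pred)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    flip <- compute_metrics(truth, -pred)
    cnt <- m$counts
    degenerate <- any(c(cnt["TP"] + cnt["FP"], cnt["TP"] + cnt["FN"],
                        cnt["TN"] + cnt["FP"], cnt["TN"] + cnt["FN"]) == 0)
    if (!degenerate) expect_equal(flip$mcc, -m$mcc, tolerance = 1e-12)
  }
})

test_that("ROC/AUC reproduce the worked rank-statistic cases", {
  r1 <- roc_auc(c(1, 1, -1, -1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(r1$auc, 1)

  r2 <- roc_auc(c(1, -1, 1, -1), rep(0.4, 4))
  expect_equal(r2$auc, 0.5)

  # concordant pairs 3 of 4
  r3 <- roc_auc(c(1, -1, 1, -1), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(r3$auc, 0.75)

  expect_error(roc_auc(c(1, 1), c(0.3, 0.2)), "AUC undefined")
})

test_that("ROC curves run from (0,0) to (1,1) with monotone coordinates", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    truth <- c(1L, -1L, sample(c(1L, -1L), n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    r <- roc_auc(truth, scores)
    p <- r$points
    expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
    expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
    expect_true(all(diff(p$fpr) >= 0))
    expect_true(all(diff(p$tpr) >= 0))
    # rank AUC equals the trapezoidal area under the tie-aware curve
    trap <- sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC matches pROC and is invariant to monotone transforms and relabeling", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    truth <- c(1L, -1L, sample(c(1L, -1L), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)
    mine <- roc_auc(truth, scores)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(response = truth, predictor = scores,
                levels = c("-1", "1"), direction = "<"))))
    expect_equal(mine, ref, tolerance = 1e-12)
    expect_equal(roc_auc(truth, exp(3 * scores))$auc, mine,
                 tolerance = 1e-12)
    expect_equal(roc_auc(-truth, -scores)$auc, mine, tolerance = 1e-12)
  }
})
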