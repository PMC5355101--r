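test_that("default grids enumerate the documented candidate lists", {
  g <- build_grid("DNA")
  expect_identical(nrow(g$candidates), 1250L)
  expect_identical(unique(g$candidates$k), c(2L, 3L))
  expect_identical(unique(g$candidates$mode), "parallel")
  expect_equal(unique(g$candidates$C), 2^c(-2, 0, 2, 4, 6))
  expect_equal(unique(g$candidates$gamma), 2^c(-6, -4, -2, 0, 2))

  gp <- build_grid("PROTEIN")
  expect_identical(unique(gp$candidates$k), 1L)

  single <- build_grid("DNA", k = 2, lambda = 1, w = 0.5, C = 1, gamma = 1)
  expect_identical(nrow(single$candidates), 1L)

  # lexicographic candidate order in (k, lambda, w, mode, C, gamma)
  expect_true(!is.unsorted(g$candidates$k))
  first_k <- g$candidates[g$candidates$k == 2L, ]
  expect_true(!is.unsorted(first_k$lambda))
  expect_identical(g$candidates$gamma[1:5], 2^c(-6, -4, -2, 0, 2))
})

test_that("grid construction validates candidate values", {
  expect_error(build_grid("DNA", w = c(0, 0.5)), "w must be > 0")
  expect_error(build_grid("DNA", C = numeric(0)), "empty candidate list")
  expect_error(build_grid("DNA", gamma = -2), "gamma must be > 0")
  expect_error(build_grid("DNA", lambda = -1), "lambda must be >= 0")
})

test_that("search evaluates every admissible candidate and respects the tie rule", {
  b <- separable_benchmark(n = 6, L = 40)
  idx <- builtin_properties("DNA")
  folds <- make_folds(b$dataset$labels, 3, seed = 1)

  single <- build_grid("DNA", k = 2, lambda = 1, w = 0.5, C = 1, gamma = 1)
  r1 <- grid_search(b$dataset, single, folds, idx)
  expect_identical(r1$best, 1L)
  expect_identical(r1$n_evaluated, 1L)

  # perfectly separable: many candidates reach the same objective, so the
  # lexicographically earliest (simplest) must win
  g <- build_grid("DNA", k = 2, lambda = c(1, 2), w = 0.5, C = c(1, 4),
                  gamma = c(0.25, 1))
  r <- grid_search(b$dataset, g, folds, idx)
  top <- which(r$table$acc == max(r$table$acc))
  expect_identical(r$best, top[1])
})

test_that("inadmissible candidates are skipped with a reason, or fail the search when universal", {
  short <- make_dataset(
    read_fasta(write_tmp_fasta(list(p1 = "ACGTAC", p2 = "GGCCAA")), "DNA"),
    read_fasta(write_tmp_fasta(list(n1 = "TTTTGG", n2 = "CACAGT")), "DNA"))
  idx <- builtin_properties("DNA")
  folds <- make_folds(short$labels, 2, seed = 1)
  g <- build_grid("DNA", k = 2, lambda = c(2, 10), w = 0.5, C = 1, gamma = 1)
  expect_message(r <- grid_search(short, g, folds, idx), "skipped")
  expect_identical(r$n_evaluated, 1L)
  expect_false(r$table$evaluated[r$table$lambda == 10L])
  expect_identical(r$table$k[r$best], 2L)

  g_bad <- build_grid("DNA", k = 2, lambda = 10, w = 0.5, C = 1, gamma = 1)
  expect_error(grid_search(short, g_bad, folds, idx), "no admissible")
})

test_that("search results are invariant to the worker count", {
  b <- separable_benchmark(n = 8, L = 50, seed = 31)
  idx <- builtin_properties("DNA")
  folds <- make_folds(b$dataset$labels, 4, seed = 9)
  g <- build_grid("DNA", k = c(2, 3), lambda = c(1, 2), w = 0.5,
                  C = c(1, 4), gamma = c(0.25, 1))
  r1 <- grid_search(b$dataset, g, folds, idx, n_workers = 1)
  r4 <- grid_search(b$dataset, g, folds, idx, n_workers = 4)
  expect_identical(r1$table, r4$table)
  expect_identical(r1$best, r4$best)

  p1 <- tempfile(); p4 <- tempfile()
  write_grid_report(r1, p1); write_grid_report(r4, p4)
  expect_identical(readLines(p1), readLines(p4))
})

test_that("enlarging the grid never decreases the winning objective", {
  b <- separable_benchmark(n = 6, L = 40, seed = 77)
  idx <- builtin_properties("DNA")
  folds <- make_folds(b$dataset$labels, 3, seed = 2)
  small <- build_grid("DNA", k = 2, lambda = 1, w = 0.5, C = 1,
                      gamma = 0.0625)
  big <- build_grid("DNA", k = 2, lambda = c(1, 3), w = 0.5, C = c(1, 16),
                    gamma = c(0.0625, 1))
  rs <- grid_search(b$dataset, small, folds, idx)
  rb <- grid_search(b$dataset, big, folds, idx)
  expect_gte(rb$table$acc[rb$best], rs$table$acc[rs$best])
})

test_that("objective switches which candidate wins", {
  b <- synth_benchmark("DNA", n_per_class = 12, length = 60,
                       signal = "motif", insertion_prob = 0.8, seed = 15)
  idx <- builtin_properties("DNA")
  folds <- make_folds(b$dataset$labels, 3, seed = 3)
  g_auc <- build_grid("DNA", k = 2, lambda = 1, w = 0.5, C = c(0.25, 4),
                      gamma = c(0.0625, 1), objective = "auc")
  r <- grid_search(b$dataset, g_auc, folds, idx)
  expect_identical(r$table$auc[r$best], max(r$table$auc, na.rm = TRUE))
})
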