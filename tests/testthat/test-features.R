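test_that("k-mer composition counts overlapping windows in lexicographic order", {
  expect_equal(kmer_composition("ACGA", 1, "DNA"),
               c(A = 0.5, C = 0.25, G = 0.25, T = 0), tolerance = 1e-15)

  v2 <- kmer_composition("ACGA", 2, "DNA")
  expect_length(v2, 16L)
  expect_identical(names(v2)[1:5], c("AA", "AC", "AG", "AT", "CA"))
  expect_equal(unname(v2[c("AC", "CG", "GA")]), rep(1 / 3, 3),
               tolerance = 1e-15)
  expect_equal(sum(v2), 1, tolerance = 1e-15)
  expect_equal(sum(v2 > 0), 3L)

  v_homo <- kmer_composition("AAAAA", 2, "DNA")
  expect_equal(unname(v_homo["AA"]), 1)
  expect_equal(sum(v_homo), 1)

  expect_error(kmer_composition("AC", 3, "DNA"), "shorter than k")
})

test_that("parallel correlation reproduces hand-derived worked cases", {
  # homopolymer: Theta(a, a) = 0 at every tier
  idx_dna <- builtin_properties("DNA")
  expect_equal(parallel_correlation("AAAAAA", idx_dna, 3), rep(0, 3),
               tolerance = 1e-15)

  # single property with P(A) = -1, P(G) = +1: theta_1 of "AG" is (1-(-1))^2 = 4
  idx_toy <- toy_index("PROTEIN", list(A = -1, G = 1))
  expect_equal(parallel_correlation("AG", idx_toy, 1), 4, tolerance = 1e-15)

  expect_identical(parallel_correlation("ACGT", idx_dna, 0), numeric(0))
  err <- expect_error(parallel_correlation("ACG", idx_dna, 5, id = "shorty"))
  expect_match(conditionMessage(err), "shorty")
  expect_match(conditionMessage(err), "max lambda=1")
})

test_that("series correlation reproduces hand-derived worked cases", {
  idx_toy <- toy_index("PROTEIN", list(A = -1, G = 1))
  expect_equal(series_correlation("AG", idx_toy, 1), -1, tolerance = 1e-15)
  expect_equal(series_correlation("GGGG", idx_toy, 1), 1, tolerance = 1e-15)
  # two tiers, one property: ("AGAG", lag 1) -> mean(-1,-1,-1) = -1;
  # lag 2 -> mean(+1,+1) = +1
  expect_equal(series_correlation("AGAG", idx_toy, 2), c(-1, 1),
               tolerance = 1e-15)
})

test_that("correlation factors agree with the naive double-loop oracle", {
  set.seed(91)
  cases <- 0L
  for (rep in 1:70) {
    mol <- sample(c("DNA", "RNA", "PROTEIN"), 1)
    L <- sample(15:40, 1)
    n_props <- sample(1:6, 1)
    idx <- standardize_properties(random_property_table(mol, n_props))
    seq <- random_seq(L, mol)
    lambda <- sample(1:5, 1)
    expect_equal(parallel_correlation(seq, idx, lambda),
                 naive_theta(seq, idx, lambda), tolerance = 1e-10)
    expect_equal(series_correlation(seq, idx, lambda),
                 naive_tau(seq, idx, lambda), tolerance = 1e-10)
    cases <- cases + 2L
  }
  expect_gte(cases, 140L)
})

test_that("pse vectors normalize to sum 1 and reduce correctly", {
  # homopolymer protein, parallel: T = 0, vector equals composition
  idx_p <- builtin_properties("PROTEIN")
  v <- pse_vector("AAAAA", pse_params(1, 2, 0.5, "parallel"), idx_p)
  expect_length(v, 22L)
  expect_equal(unname(v["A"]), 1, tolerance = 1e-12)
  expect_equal(unname(v[c("pse.1", "pse.2")]), c(0, 0), tolerance = 1e-15)

  # lambda = 0 reduces exactly to the k-mer composition
  idx_d <- builtin_properties("DNA")
  s <- random_seq(30, "DNA")
  expect_identical(unname(pse_vector(s, pse_params(2, 0, 0.7), idx_d)),
                   unname(kmer_composition(s, 2, "DNA")))

  # dimension bookkeeping: parallel M + lambda, series M + lambda * Lambda
  expect_length(pse_vector(s, pse_params(2, 3, 0.5, "parallel"), idx_d),
                16L + 3L)
  expect_length(pse_vector(s, pse_params(2, 3, 0.5, "series"), idx_d),
                16L + 3L * 6L)
  expect_identical(names(pse_vector(s, pse_params(1, 1, 0.5, "series"),
                                    idx_d))[5:6],
                   c("pse.1.1", "pse.1.2"))
})

test_that("pse vector assembly matches the oracle formula on random cases", {
  set.seed(17)
  for (rep in 1:25) {
    mol <- sample(c("DNA", "RNA", "PROTEIN"), 1)
    idx <- standardize_properties(random_property_table(mol, sample(1:4, 1)))
    s <- random_seq(sample(20:35, 1), mol)
    par <- pse_params(sample(1:2, 1), sample(0:4, 1),
                      runif(1, 0.05, 1), sample(c("parallel", "series"), 1))
    f <- kmer_composition(s, par$k, mol)
    cc <- if (par$mode == "parallel") naive_theta(s, idx, par$lambda)
          else naive_tau(s, idx, par$lambda)
    if (par$lambda == 0L) cc <- numeric(0)
    if (1 + par$w * sum(cc) <= 0) next  # degenerate draw, covered elsewhere
    expected <- c(f, par$w * cc) / (1 + par$w * sum(cc))
    got <- pse_vector(s, par, idx)
    expect_equal(unname(got), unname(expected), tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("feature scale invariance: rescaling a raw property changes nothing", {
  set.seed(33)
  raw <- random_property_table("DNA", 3)
  scaled_vals <- raw$values
  scaled_vals[, 2] <- scaled_vals[, 2] * 37.5
  scaled <- property_table(scaled_vals, "DNA")
  s <- random_seq(40, "DNA")
  p <- pse_params(2, 4, 0.3, "parallel")
  expect_equal(pse_vector(s, p, standardize_properties(raw)),
               pse_vector(s, p, standardize_properties(scaled)),
               tolerance = 1e-9)
})

test_that("dataset feature extraction is row-ordered, equivariant, and strict about length", {
  b <- separable_benchmark(n = 5, L = 30)
  idx <- builtin_properties("DNA")
  p <- pse_params(2, 3, 0.5)
  feats <- extract_features(b$dataset, p, idx)
  expect_identical(dim(feats$x), c(10L, 19L))
  expect_identical(rownames(feats$x), names(b$dataset$seqs))
  expect_equal(unname(rowSums(feats$x)), rep(1, 10), tolerance = 1e-9)

  # permuting the dataset permutes rows identically
  perm <- c(3, 1, 2, 9, 10, 4:8)
  feats_p <- extract_features(b$dataset[perm], p, idx)
  expect_equal(feats_p$x, feats$x[perm, ], tolerance = 0)

  # every offending id is listed, not just the first
  short <- make_dataset(
    read_fasta(write_tmp_fasta(list(tiny1 = "ACG", tiny2 = "ACGTACGT",
                                    tiny3 = "AGT")), "DNA"),
    read_fasta(write_tmp_fasta(list(long1 = strrep("ACGT", 5))), "DNA"))
  err <- expect_error(extract_features(short, pse_params(2, 5, 0.5), idx))
  expect_match(conditionMessage(err), "tiny1")
  expect_match(conditionMessage(err), "tiny3")
})

test_that("degenerate series normalization is reported, not returned", {
  # strongly anti-correlated alternating sequence with a large weight drives
  # 1 + w * T below zero
  idx_toy <- toy_index("PROTEIN", list(A = -2, G = 2))
  expect_error(pse_vector(strrep("AG", 10), pse_params(1, 1, 1, "series"),
                          idx_toy),
               "degenerate normalization")
})
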