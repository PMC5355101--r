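# Shared fixtures: tiny FASTA writers, toy property tables, random-case
# generators, and independent brute-force oracles for the correlation
# factors (naive double loops, kept deliberately separate from the package's
# vectorized implementation).

write_tmp_fasta <- function(records, width = 0L) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    body <- if (width > 0L && nchar(s) > 0L)
      substring(s, seq(1, nchar(s), width), pmin(seq(width, nchar(s) + width - 1, width), nchar(s)))
    else s
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

random_seq <- function(L, molecule) {
  paste(sample(alphabet(molecule), L, replace = TRUE), collapse = "")
}

# toy standardized index over the full unit alphabet, with prescribed values
# at chosen symbols (rest 0); bypasses standardization so worked examples
# with hand-set property values are exact
toy_index <- function(molecule, values, n_props = 1L) {
  ua <- psepred:::unit_alphabet(molecule)
  m <- matrix(0, nrow = length(ua), ncol = n_props,
              dimnames = list(ua, paste0("toy", seq_len(n_props))))
  for (sym in names(values)) m[sym, ] <- values[[sym]]
  psepred:::new_property_table(m, molecule, standardized = TRUE, name = "toy")
}

# random raw property table covering the unit alphabet
random_property_table <- function(molecule, n_props) {
  ua <- psepred:::unit_alphabet(molecule)
  m <- matrix(rnorm(length(ua) * n_props), nrow = length(ua),
              dimnames = list(ua, paste0("p", seq_len(n_props))))
  property_table(m, molecule, name = "random")
}

naive_unit_symbols <- function(seq, molecule) {
  if (molecule == "PROTEIN") {
    strsplit(seq, "", fixed = TRUE)[[1]]
  } else {
    L <- nchar(seq)
    substring(seq, 1:(L - 1L), 2:L)
  }
}

# O(L^2 * Lambda) reference for the parallel (type-I) factors
naive_theta <- function(seq, index, lambda) {
  u <- naive_unit_symbols(seq, index$molecule)
  P <- index$values
  n <- length(u)
  Lam <- ncol(P)
  out <- numeric(lambda)
  for (j in seq_len(lambda)) {
    tot <- 0
    for (i in seq_len(n - j)) {
      s <- 0
      for (xi in seq_len(Lam))
        s <- s + (P[u[i], xi] - P[u[i + j], xi])^2
      tot <- tot + s / Lam
    }
    out[j] <- tot / (n - j)
  }
  out
}

# O(L^2 * Lambda) reference for the series (type-II) factors
naive_tau <- function(seq, index, lambda) {
  u <- naive_unit_symbols(seq, index$molecule)
  P <- index$values
  n <- length(u)
  Lam <- ncol(P)
  out <- numeric(lambda * Lam)
  for (j in seq_len(lambda)) {
    for (xi in seq_len(Lam)) {
      tot <- 0
      for (i in seq_len(n - j))
        tot <- tot + P[u[i], xi] * P[u[i + j], xi]
      out[(j - 1L) * Lam + xi] <- tot / (n - j)
    }
  }
  out
}

# small well-separated 2-D point clouds for SVM unit tests
toy_clouds <- function(n = 10, gap = 4) {
  x <- rbind(matrix(rnorm(2 * n, mean = 0), ncol = 2),
             matrix(rnorm(2 * n, mean = gap), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(-1L, 1L), each = n))
}

# strongly separable sequence benchmark (large composition shift)
separable_benchmark <- function(n = 10, L = 80, seed = 42) {
  synth_benchmark("DNA", n_per_class = n, length = L,
                  signal = "composition_shift", shift_delta = 0.6,
                  seed = seed)
}
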