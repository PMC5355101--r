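# PseKNC / PseAAC feature vectors: a k-mer composition block of dimension
# |alphabet|^k plus lambda pseudo components built from physicochemical
# correlation factors. DNA/RNA correlations always use the dinucleotide unit
# (k only sets the composition block); protein uses the residue unit.

#' Pseudo-component feature hyperparameters
#'
#' @param k Tuple size of the composition block (protein classically 1,
#'   nucleotides 2 or 3).
#' @param lambda Number of correlation tiers (maximum unit lag) contributing
#'   pseudo components; 0 reduces the vector to plain k-mer composition.
#' @param w Positive weight balancing the pseudo block against the
#'   composition block before joint normalization.
#' @param mode `"parallel"` (type-I: property-averaged squared differences,
#'   one factor per tier) or `"series"` (type-II: per-property products,
#'   lambda x Lambda factors).
#' @return A `pse_params` object.
#' @export
pse_params <- function(k = 2L, lambda = 0L, w = 0.5, mode = c("parallel", "series")) {
  mode <- match.arg(mode)
  k <- as.integer(k); lambda <- as.integer(lambda)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (is.na(lambda) || lambda < 0L)
    stop("lambda must be a non-negative integer", call. = FALSE)
  if (!is.finite(w) || w <= 0) stop("w must be > 0", call. = FALSE)
  structure(list(k = k, lambda = lambda, w = w, mode = mode),
            class = "pse_params")
}

#' @export
print.pse_params <- function(x, ...) {
  cat(sprintf("pse_params: k=%d lambda=%d w=%g mode=%s\n",
              x$k, x$lambda, x$w, x$mode), sep = "")
  invisible(x)
}

# number of correlation units in a sequence of length L
n_units <- function(L, molecule) {
  if (match_molecule(molecule) == "PROTEIN") L else L - 1L
}

#' Maximum admissible lambda for a sequence length
#'
#' Every correlation tier must average at least one term: lambda <= L-2 for
#' the dinucleotide unit (DNA/RNA), lambda <= L-1 for the residue unit.
#'
#' @param L Sequence length.
#' @param molecule Molecule type.
#' @return Integer maximum lambda (possibly negative for degenerate L).
#' @export
max_lambda <- function(L, molecule) n_units(as.integer(L), molecule) - 1L

all_kmers <- function(molecule, k) {
  ab <- alphabet(molecule)
  if (k == 1L) return(ab)
  g <- expand.grid(rev(rep(list(ab), k)), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  do.call(paste0, rev(g))  # last position varies fastest => lexicographic
}

#' Overlapping k-mer composition of a sequence
#'
#' Component for k-mer m is its count among the L-k+1 overlapping windows
#' divided by L-k+1; components are ordered lexicographically over the
#' canonical alphabet order and sum to 1.
#'
#' @param seq Residue string (single sequence).
#' @param k Tuple size.
#' @param molecule Molecule type.
#' @return Named numeric vector of length `|alphabet|^k`.
#' @export
#' @examples
#' kmer_composition("ACGA", 1, "DNA")
kmer_composition <- function(seq, k, molecule) {
  seq <- as.character(seq)[1]
  k <- as.integer(k)
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k (L=", L, ", k=", k, ")",
                  call. = FALSE)
  kmers <- all_kmers(molecule, k)
  windows <- substring(seq, 1:(L - k + 1L), k:L)
  counts <- table(factor(windows, levels = kmers))
  out <- as.numeric(counts) / (L - k + 1L)
  names(out) <- kmers
  out
}

# (n_units x Lambda) matrix of standardized property values along a sequence
unit_property_matrix <- function(seq, index) {
  molecule <- index$molecule
  L <- nchar(seq)
  if (index$unit == "dinucleotide") {
    if (L < 2L) stop("sequence too short for dinucleotide unit", call. = FALSE)
    units <- substring(seq, 1:(L - 1L), 2:L)
  } else {
    units <- strsplit(seq, "", fixed = TRUE)[[1]]
  }
  idx <- match(units, rownames(index$values))
  if (anyNA(idx))
    stop("symbol not covered by property index: ",
         units[which(is.na(idx))[1]], call. = FALSE)
  index$values[idx, , drop = FALSE]
}

check_index <- function(index) {
  if (!inherits(index, "pse_property_index"))
    stop("a standardized property index is required; ",
         "run standardize_properties() on the table first", call. = FALSE)
  invisible(index)
}

check_lambda <- function(lambda, L, molecule, id = "<sequence>") {
  mx <- max_lambda(L, molecule)
  if (lambda > mx)
    stop(sprintf("lambda=%d inadmissible for sequence '%s' (L=%d, max lambda=%d)",
                 lambda, id, L, mx), call. = FALSE)
}

#' Parallel (type-I) correlation factors
#'
#' Tier factor \eqn{\theta_j} is the mean over positions i of
#' \eqn{\Theta(u_i, u_{i+j})}, where
#' \eqn{\Theta(a,b) = \frac{1}{\Lambda}\sum_\xi (P_\xi(a)-P_\xi(b))^2} averages
#' squared standardized property differences; units u are dinucleotides
#' (DNA/RNA) or residues (protein).
#'
#' @param seq Residue string.
#' @param index A standardized `pse_property_index`.
#' @param lambda Number of tiers.
#' @param id Sequence id used in error messages.
#' @return Numeric vector `theta_1..theta_lambda` (each >= 0; empty for
#'   lambda = 0).
#' @export
parallel_correlation <- function(seq, index, lambda, id = "<sequence>") {
  check_index(index)
  lambda <- as.integer(lambda)
  if (lambda == 0L) return(numeric(0))
  check_lambda(lambda, nchar(seq), index$molecule, id)
  P <- unit_property_matrix(seq, index)
  n <- nrow(P)
  vapply(seq_len(lambda), function(j) {
    d <- P[1:(n - j), , drop = FALSE] - P[(1L + j):n, , drop = FALSE]
    sum(d * d) / ((n - j) * ncol(P))
  }, numeric(1))
}

#' Series (type-II) correlation factors
#'
#' Per-property product correlations: factor \eqn{\tau_{(j-1)\Lambda+\xi}} is
#' the mean over positions i of \eqn{P_\xi(u_i)\,P_\xi(u_{i+j})}, tiers
#' j = 1..lambda nested outside properties \eqn{\xi = 1..\Lambda}. Values may
#' be negative.
#'
#' @inheritParams parallel_correlation
#' @return Numeric vector of length `lambda * Lambda`.
#' @export
series_correlation <- function(seq, index, lambda, id = "<sequence>") {
  check_index(index)
  lambda <- as.integer(lambda)
  if (lambda == 0L) return(numeric(0))
  check_lambda(lambda, nchar(seq), index$molecule, id)
  P <- unit_property_matrix(seq, index)
  n <- nrow(P)
  out <- lapply(seq_len(lambda), function(j) {
    colMeans(P[1:(n - j), , drop = FALSE] * P[(1L + j):n, , drop = FALSE])
  })
  unlist(out, use.names = FALSE)
}

pse_feature_names <- function(molecule, params, index) {
  km <- all_kmers(molecule, params$k)
  if (params$lambda == 0L) return(km)
  ps <- if (params$mode == "parallel") {
    paste0("pse.", seq_len(params$lambda))
  } else {
    as.vector(t(outer(seq_len(params$lambda), seq_len(ncol(index$values)),
                      function(j, xi) paste0("pse.", j, ".", xi))))
  }
  c(km, ps)
}

#' Pseudo-component feature vector of one sequence
#'
#' Assembles the k-mer composition block f (sums to 1) and the correlation
#' factors c (theta or tau): with T the sum of all factors, composition
#' component u is \eqn{f_u/(1+wT)} and pseudo component j is
#' \eqn{w c_j/(1+wT)}, so the whole vector sums to 1.
#'
#' @inheritParams parallel_correlation
#' @param params A [pse_params()] object.
#' @return Named numeric vector of dimension `|alphabet|^k + lambda`
#'   (parallel) or `|alphabet|^k + lambda*Lambda` (series).
#' @export
pse_vector <- function(seq, params, index, id = "<sequence>") {
  stopifnot(inherits(params, "pse_params"))
  check_index(index)
  f <- kmer_composition(seq, params$k, index$molecule)
  cc <- if (params$mode == "parallel") {
    parallel_correlation(seq, index, params$lambda, id)
  } else {
    series_correlation(seq, index, params$lambda, id)
  }
  denom <- 1 + params$w * sum(cc)
  if (denom <= 0)
    stop("degenerate normalization (1 + w*T <= 0) for '", id, "'",
         call. = FALSE)
  out <- c(f, params$w * cc) / denom
  names(out) <- pse_feature_names(index$molecule, params, index)
  out
}

#' Feature matrix and labels for a whole dataset
#'
#' Row i is the [pse_vector()] of sequence i, in dataset order.
#'
#' @param dataset A `pse_dataset`.
#' @param params A [pse_params()] object.
#' @param index A standardized `pse_property_index`.
#' @return List with `x` (numeric matrix, rownames = ids) and `y`
#'   (+1/-1 integer labels).
#' @export
extract_features <- function(dataset, params, index) {
  stopifnot(inherits(dataset, "pse_dataset"))
  check_index(index)
  seqs <- unclass(dataset$seqs)
  ids <- names(dataset$seqs)
  L <- nchar(seqs)
  bad <- L < params$k | params$lambda > max_lambda(L, dataset$molecule)
  if (any(bad))
    stop("parameters (k=", params$k, ", lambda=", params$lambda,
         ") inadmissible for sequence(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  rows <- lapply(seq_along(seqs), function(i)
    pse_vector(seqs[i], params, index, id = ids[i]))
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  list(x = x, y = dataset$labels)
}
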