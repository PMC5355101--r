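# Seeded two-class benchmark generator with controllable planted signal.
# Per-sequence randomness is derived from the master seed by counter-based
# sub-seeding, so adding sequences never perturbs earlier ones.

seq_subseed <- function(seed, counter) {
  s <- (as.numeric(seed) %% 65536) * 32749 + 7919 * as.numeric(counter)
  as.integer(s %% 2147483647)
}

random_sequence <- function(L, prob, ab) {
  paste(sample(ab, L, replace = TRUE, prob = prob), collapse = "")
}

#' Generate a synthetic two-class sequence benchmark
#'
#' Three signal regimes: `"motif"` plants a fixed motif at a uniform random
#' position in each positive sequence (with probability `insertion_prob`,
#' overwriting the background so lengths are unchanged); negatives are
#' i.i.d. uniform. `"composition_shift"` tilts the positive class's symbol
#' frequencies: the first alphabet symbol's probability is raised by
#' `shift_delta` and the vector renormalized. `"null"` draws both classes
#' i.i.d. uniform, so labels carry no signal.
#'
#' @param molecule `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param n_per_class Sequences per class.
#' @param length Sequence length L.
#' @param signal `"motif"`, `"composition_shift"` or `"null"`.
#' @param motif Motif string over the molecule's alphabet (signal = motif).
#' @param insertion_prob Probability that a positive receives the motif.
#' @param shift_delta Added probability mass on the first alphabet symbol
#'   (signal = composition_shift).
#' @param seed Master integer seed; generation is fully reproducible.
#' @return List with `dataset` (a `pse_dataset`) and `manifest` (data.frame
#'   of id, label, and the planted 1-based motif start, NA when none).
#' @export
#' @examples
#' b <- synth_benchmark("DNA", n_per_class = 5, length = 40, seed = 1)
#' b$dataset
#' head(b$manifest)
synth_benchmark <- function(molecule = "DNA", n_per_class = 100L,
                            length = 100L,
                            signal = c("motif", "composition_shift", "null"),
                            motif = "ACGTACGT", insertion_prob = 1,
                            shift_delta = 0.1, seed = 1L) {
  molecule <- match_molecule(molecule)
  signal <- match.arg(signal)
  ab <- alphabet(molecule)
  L <- as.integer(length)
  n <- as.integer(n_per_class)
  stopifnot(n >= 1L, L >= 1L)
  if (signal == "motif") {
    motif <- toupper(motif)
    msym <- strsplit(motif, "", fixed = TRUE)[[1]]
    if (!all(msym %in% ab))
      stop("motif contains symbols outside the ", molecule, " alphabet",
           call. = FALSE)
    if (nchar(motif) > L)
      stop("motif longer than sequence length", call. = FALSE)
    if (insertion_prob < 0 || insertion_prob > 1)
      stop("insertion_prob must be in [0, 1]", call. = FALSE)
  }
  unif <- rep(1 / length(ab), length(ab))
  pos_prob <- if (signal == "composition_shift") {
    p <- unif; p[1] <- p[1] + shift_delta
    if (any(p < 0)) stop("shift_delta drives a probability negative",
                         call. = FALSE)
    p / sum(p)
  } else unif
  ids <- c(sprintf("pos_%04d", seq_len(n)), sprintf("neg_%04d", seq_len(n)))
  labels <- rep(c(1L, -1L), each = n)
  seqs <- character(2L * n)
  motif_start <- rep(NA_integer_, 2L * n)
  for (i in seq_len(2L * n)) {
    positive <- labels[i] == 1L
    with_seed(seq_subseed(seed, i), {
      seqs[i] <- random_sequence(L, if (positive) pos_prob else unif, ab)
      if (positive && signal == "motif" && stats::runif(1) <= insertion_prob) {
        start <- sample.int(L - nchar(motif) + 1L, 1L)
        substr(seqs[i], start, start + nchar(motif) - 1L) <- motif
        motif_start[i] <- start
      }
    })
  }
  dataset <- new_dataset(new_seqs(seqs, ids, molecule), labels)
  manifest <- data.frame(id = ids, label = labels, motif_start = motif_start,
                         stringsAsFactors = FALSE)
  list(dataset = dataset, manifest = manifest)
}
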