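#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
NULL

new_seqs <- function(seq, id, molecule) {
  stopifnot(length(seq) == length(id))
  structure(as.character(seq), names = as.character(id),
            molecule = molecule, class = "pse_seqs")
}

#' @export
print.pse_seqs <- function(x, ...) {
  cat(sprintf("%s sequence set: %d record(s), lengths %s\n",
              attr(x, "molecule"), length(x),
              if (length(x)) paste0(min(nchar(x)), "-", max(nchar(x))) else "-"))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s  %s%s\n", names(x)[i],
                substr(s, 1, 50), if (nchar(s) > 50) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... %d more\n", length(x) - n))
  invisible(x)
}

validate_residues <- function(seq, id, molecule, skip_invalid = FALSE) {
  ab <- alphabet(molecule)
  keep <- rep(TRUE, length(seq))
  for (i in seq_along(seq)) {
    if (nchar(seq[i]) == 0L)
      stop("empty sequence for ", id[i], call. = FALSE)
    sym <- strsplit(seq[i], "", fixed = TRUE)[[1]]
    bad <- which(!(sym %in% ab))
    if (length(bad)) {
      if (skip_invalid) {
        keep[i] <- FALSE
      } else {
        stop(sprintf(
          "invalid symbol '%s' at position %d in record '%s' (not in %s alphabet)",
          sym[bad[1]], bad[1], id[i], molecule), call. = FALSE)
      }
    }
  }
  if (!all(keep))
    message(sprintf("skipped %d record(s) with out-of-alphabet symbols",
                    sum(!keep)))
  list(seq = seq[keep], id = id[keep])
}

#' Read a FASTA file of validated sequences
#'
#' Reads multi-line FASTA, concatenates sequence lines, strips whitespace and
#' uppercases. Every residue must belong to the declared molecule's alphabet;
#' ambiguity codes (N, X, gaps, ...) are rejected rather than dropped, since
#' silent deletion would change the correlation lags of downstream features.
#'
#' @param path Path to a FASTA file.
#' @param molecule `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param skip_invalid Drop whole records containing out-of-alphabet symbols
#'   (with a logged count) instead of raising an error.
#' @return A `pse_seqs` object: named character vector of residue strings
#'   (names are the FASTA header tokens up to the first whitespace) with a
#'   `molecule` attribute, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt", ">s2", "ACGT"), fa)
#' read_fasta(fa, "DNA")
read_fasta <- function(path, molecule, skip_invalid = FALSE) {
  molecule <- match_molecule(molecule)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("[ \t]", "", as.character(set)))
  v <- validate_residues(seqs, ids, molecule, skip_invalid = skip_invalid)
  if (length(v$seq) == 0L)
    stop("no valid records left in ", path, call. = FALSE)
  new_seqs(v$seq, v$id, molecule)
}

#' Write sequences to FASTA
#'
#' @param seqs A `pse_seqs` object.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(inherits(seqs, "pse_seqs"))
  set <- Biostrings::BStringSet(unclass(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

new_dataset <- function(seqs, labels) {
  stopifnot(inherits(seqs, "pse_seqs"), length(seqs) == length(labels),
            all(labels %in% c(1L, -1L)))
  structure(list(seqs = seqs, labels = as.integer(labels),
                 molecule = attr(seqs, "molecule")),
            class = "pse_dataset")
}

#' Assemble a labeled two-class dataset from sequence sets
#'
#' @param pos,neg `pse_seqs` of the same molecule type; positives get label
#'   `+1`, negatives `-1`, in that order, original ordering preserved.
#' @return A `pse_dataset`: list with `seqs`, `labels` (+1/-1) and `molecule`.
#' @export
make_dataset <- function(pos, neg) {
  stopifnot(inherits(pos, "pse_seqs"), inherits(neg, "pse_seqs"))
  if (!identical(attr(pos, "molecule"), attr(neg, "molecule")))
    stop("positive and negative sets have different molecule types",
         call. = FALSE)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("benchmark requires both classes", call. = FALSE)
  dup <- intersect(names(pos), names(neg))
  if (length(dup))
    warning("id(s) present in both classes: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "", call. = FALSE)
  seqs <- new_seqs(c(unclass(pos), unclass(neg)),
                   c(names(pos), names(neg)), attr(pos, "molecule"))
  new_dataset(seqs, rep(c(1L, -1L), c(length(pos), length(neg))))
}

#' Load a positive/negative FASTA benchmark
#'
#' The benchmark convention is two FASTA files: one per class. Positives are
#' labeled `+1` then negatives `-1`; duplicate ids across the files are
#' permitted but produce a warning.
#'
#' @inheritParams read_fasta
#' @param pos_path,neg_path FASTA paths for the positive and negative class.
#' @return A `pse_dataset`.
#' @export
load_benchmark <- function(pos_path, neg_path, molecule, skip_invalid = FALSE) {
  molecule <- match_molecule(molecule)
  pos <- read_fasta(pos_path, molecule, skip_invalid = skip_invalid)
  neg <- read_fasta(neg_path, molecule, skip_invalid = skip_invalid)
  make_dataset(pos, neg)
}

#' @export
print.pse_dataset <- function(x, ...) {
  cat(sprintf("%s benchmark: %d positive, %d negative\n", x$molecule,
              sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

#' Subset a labeled dataset by record index
#'
#' @param x A `pse_dataset`.
#' @param i Integer or logical index over records.
#' @param ... Ignored.
#' @export
`[.pse_dataset` <- function(x, i, ...) {
  s <- unclass(x$seqs)[i]
  new_dataset(new_seqs(s, names(x$seqs)[i], x$molecule), x$labels[i])
}
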