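# Canonical alphabets. File name keeps these ahead of the rest of the
# package in collation order.

MOLECULES <- c("DNA", "RNA", "PROTEIN")

ALPHABETS <- list(
  DNA     = c("A", "C", "G", "T"),
  RNA     = c("A", "C", "G", "U"),
  PROTEIN = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

match_molecule <- function(molecule) {
  match.arg(toupper(molecule), MOLECULES)
}

#' Alphabet of a molecule type
#'
#' Canonical one-letter alphabet, in the order used for k-mer columns
#' (A < C < G < T, A < C < G < U, or alphabetical amino acids).
#'
#' @param molecule `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @return Character vector of symbols.
#' @export
alphabet <- function(molecule) {
  ALPHABETS[[match_molecule(molecule)]]
}
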