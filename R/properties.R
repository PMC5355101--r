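# Physicochemical property tables: raw values per unit symbol (dinucleotide
# for DNA/RNA, residue for protein), standardized to mean 0 / population SD 1
# over the unit alphabet before any correlation is computed.

unit_alphabet <- function(molecule) {
  molecule <- match_molecule(molecule)
  if (molecule == "PROTEIN") return(ALPHABETS$PROTEIN)
  ab <- ALPHABETS[[molecule]]
  as.vector(t(outer(ab, ab, paste0)))  # AA, AC, AG, AT, CA, ... lexicographic
}

new_property_table <- function(values, molecule, standardized = FALSE,
                               name = "custom") {
  molecule <- match_molecule(molecule)
  unit <- if (molecule == "PROTEIN") "residue" else "dinucleotide"
  ua <- unit_alphabet(molecule)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("property table needs symbol rownames and property colnames",
         call. = FALSE)
  missing <- setdiff(ua, rownames(values))
  if (length(missing))
    stop("property table does not cover the full ", unit, " alphabet; ",
         "missing: ", paste(utils::head(missing, 4), collapse = ", "),
         call. = FALSE)
  values <- values[ua, , drop = FALSE]
  if (!all(is.finite(values))) stop("non-finite property values", call. = FALSE)
  structure(list(values = values, molecule = molecule, unit = unit,
                 name = name, standardized = standardized),
            class = if (standardized) c("pse_property_index",
                                        "pse_property_table")
                    else "pse_property_table")
}

#' Standardize a physicochemical property table
#'
#' Each property \eqn{\xi} is centered and scaled over the unit alphabet:
#' \eqn{P_\xi(s) = (P^0_\xi(s) - \mu_\xi)/\sigma_\xi}, with \eqn{\sigma_\xi}
#' the population standard deviation (divide by alphabet size). After
#' standardization every property has mean 0 and population SD 1, which makes
#' correlation features invariant to the units of the raw scales.
#'
#' @param table A `pse_property_table` (see [property_table()] or
#'   [builtin_properties()]).
#' @return A `pse_property_index` with standardized values.
#' @export
standardize_properties <- function(table) {
  stopifnot(inherits(table, "pse_property_table"))
  v <- table$values
  mu <- colMeans(v)
  sdev <- sqrt(colMeans(sweep(v, 2, mu)^2))
  if (any(sdev == 0))
    stop("constant property cannot be standardized: ",
         paste(colnames(v)[sdev == 0], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(v, 2, mu), 2, sdev, "/")
  new_property_table(z, table$molecule, standardized = TRUE,
                     name = table$name)
}

#' Build a property table from a symbol-by-property matrix
#'
#' @param values Numeric matrix or data frame; rownames are unit symbols
#'   (16 dinucleotides for DNA/RNA, 20 residues for protein), columns are
#'   properties.
#' @param molecule `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param name Identifier recorded in model recipes.
#' @return A `pse_property_table` of raw values.
#' @export
property_table <- function(values, molecule, name = "custom") {
  new_property_table(values, molecule, standardized = FALSE, name = name)
}

#' Read a user property table from a delimited file
#'
#' Tab-separated with a header row of property names; first column holds the
#' unit symbols. The table must cover the full unit alphabet.
#'
#' @inheritParams property_table
#' @param path Path to the TSV file.
#' @return A `pse_property_table`.
#' @export
read_property_table <- function(path, molecule, name = basename(path)) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("property table needs a symbol column plus at least ",
                        "one property column", call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- toupper(as.character(d[[1]]))
  property_table(m, molecule, name = name)
}

#' @export
print.pse_property_table <- function(x, ...) {
  cat(sprintf("%s property table '%s' (%s unit): %d properties%s\n",
              x$molecule, x$name, x$unit, ncol(x$values),
              if (x$standardized) ", standardized" else ""))
  cat("  ", paste(colnames(x$values), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Six helical dinucleotide parameters (Twist, Tilt, Roll, Shift, Slide, Rise)
# as shipped, already on a standardized scale, throughout the PseKNC
# literature and toolchain. Values are re-standardized at use anyway, so only
# their relative pattern matters.
DNA_PROPS_RAW <- local({
  m <- matrix(c(
    #    Twist   Tilt   Roll  Shift  Slide   Rise
    0.06,  0.50,  0.27,  1.59,  0.11,  0.11,  # AA
    1.50,  0.50,  0.80,  0.13,  1.29,  1.04,  # AC
    0.78,  0.36,  0.09,  0.68, -0.24, -0.62,  # AG
    1.07,  0.22,  0.62, -1.02,  2.51,  1.17,  # AT
   -1.38, -1.36, -0.27, -0.86, -0.62, -1.25,  # CA
    0.06,  1.08,  0.78,  0.22, -0.05,  0.01,  # CC
   -1.66, -1.22, -0.44, -1.38, -0.82, -1.39,  # CG
    0.78,  0.36,  0.09,  0.68, -0.24, -0.62,  # CT
   -0.08,  0.50,  0.27,  0.13, -0.39,  0.71,  # GA
   -0.08,  0.22,  1.33, -0.35,  0.65,  1.59,  # GC
    0.06,  1.08,  0.78,  0.22, -0.05,  0.01,  # GG
    1.50,  0.50,  0.80,  0.13,  1.29,  1.04,  # GT
   -1.23, -2.37, -1.38, -0.05, -1.51, -1.39,  # TA
   -0.08,  0.50,  0.27,  0.13, -0.39,  0.71,  # TC
   -1.38, -1.36, -0.27, -0.86, -0.62, -1.25,  # TG
    0.06,  0.50,  0.27,  1.59,  0.11,  0.11   # TT
  ), nrow = 16, byrow = TRUE)
  dimnames(m) <- list(unit_alphabet("DNA"),
                      c("Twist", "Tilt", "Roll", "Shift", "Slide", "Rise"))
  m
})

# Ribodinucleotide helical parameters (raw, A-form) used for RNA pseudo
# components in the same toolchain; columns match the DNA set.
RNA_PROPS_RAW <- local({
  m <- matrix(c(
    #   Twist  Tilt  Roll  Shift  Slide  Rise
    31,  -0.8,  7.0, -0.08, -1.27, 3.18,  # AA
    32,   0.8,  4.8,  0.23, -1.43, 3.24,  # AC
    30,   0.5,  8.5, -0.04, -1.50, 3.30,  # AG
    33,   1.1,  7.1, -0.06, -1.36, 3.24,  # AU
    31,   1.0,  9.9,  0.11, -1.46, 3.09,  # CA
    32,   0.3,  8.7, -0.01, -1.78, 3.32,  # CC
    27,  -0.1, 12.1,  0.30, -1.89, 3.30,  # CG
    30,   0.5,  8.5, -0.04, -1.50, 3.30,  # CU
    32,   1.3,  9.4,  0.07, -1.70, 3.38,  # GA
    35,   0.0,  6.1,  0.07, -1.39, 3.22,  # GC
    32,   0.3,  8.7, -0.01, -1.78, 3.32,  # GG
    32,   0.8,  4.8,  0.23, -1.43, 3.24,  # GU
    32,  -0.2, 10.7, -0.02, -1.45, 3.26,  # UA
    32,   1.3,  9.4,  0.07, -1.70, 3.38,  # UC
    31,   1.0,  9.9,  0.11, -1.46, 3.09,  # UG
    31,  -0.8,  7.0, -0.08, -1.27, 3.18   # UU
  ), nrow = 16, byrow = TRUE)
  dimnames(m) <- list(unit_alphabet("RNA"),
                      c("Twist", "Tilt", "Roll", "Shift", "Slide", "Rise"))
  m
})

# Classic PseAAC residue scales: hydrophobicity, Hopp-Woods hydrophilicity,
# side-chain mass.
PROTEIN_PROPS_RAW <- local({
  m <- matrix(c(
    # Hydrophobicity  Hydrophilicity  SideChainMass
     0.62, -0.5,  15,   # A
     0.29, -1.0,  47,   # C
    -0.90,  3.0,  59,   # D
    -0.74,  3.0,  73,   # E
     1.19, -2.5,  91,   # F
     0.48,  0.0,   1,   # G
    -0.40, -0.5,  82,   # H
     1.38, -1.8,  57,   # I
    -1.50,  3.0,  73,   # K
     1.06, -1.8,  57,   # L
     0.64, -1.3,  75,   # M
    -0.78,  0.2,  58,   # N
     0.12,  0.0,  42,   # P
    -0.85,  0.2,  72,   # Q
    -2.53,  3.0, 101,   # R
    -0.18,  0.3,  31,   # S
    -0.05, -0.4,  45,   # T
     1.08, -1.5,  43,   # V
     0.81, -3.4, 130,   # W
     0.26, -2.3, 107    # Y
  ), nrow = 20, byrow = TRUE)
  dimnames(m) <- list(ALPHABETS$PROTEIN,
                      c("Hydrophobicity", "Hydrophilicity", "SideChainMass"))
  m
})

#' Built-in physicochemical property sets
#'
#' DNA and RNA ship six dinucleotide helical parameters (Twist, Tilt, Roll,
#' Shift, Slide, Rise); protein ships hydrophobicity, hydrophilicity and
#' side-chain mass. These are the default property sets behind PseKNC and
#' PseAAC features; supply [read_property_table()] output to use your own.
#'
#' @param molecule `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param standardized Return the standardized index (default) or raw values.
#' @return A `pse_property_index` (or raw `pse_property_table`).
#' @export
builtin_properties <- function(molecule, standardized = TRUE) {
  molecule <- match_molecule(molecule)
  raw <- switch(molecule,
                DNA = DNA_PROPS_RAW,
                RNA = RNA_PROPS_RAW,
                PROTEIN = PROTEIN_PROPS_RAW)
  tab <- new_property_table(raw, molecule, standardized = FALSE,
                            name = paste0("builtin-", tolower(molecule)))
  if (standardized) standardize_properties(tab) else tab
}
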