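#' Canonical amino-acid alphabet
#'
#' One-letter codes in the canonical order used throughout the package for all
#' 20x20 energy matrices and marginal vectors: `ARNDCQEGHILKMFPSTWYV`.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# three-letter -> one-letter, MSE treated as MET
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

aa_index <- function(aa) {
  idx <- match(aa, aa_alphabet())
  if (anyNA(idx)) {
    stop("non-canonical amino acid(s): ", paste(unique(aa[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Uniform amino-acid background probabilities
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
uniform_aa_freq <- function() {
  stats::setNames(rep(1 / 20, 20), aa_alphabet())
}

#' Amino-acid frequencies observed in a structure database
#'
#' @param db A structure (see [read_structure()]) or list of structures.
#' @return Named numeric vector over the canonical alphabet, summing to 1.
#'   Positions with unknown residue type are ignored.
#' @export
db_aa_freq <- function(db) {
  res <- bind_structures(db)
  aa <- res$aa[!is.na(res$aa)]
  if (length(aa) == 0L) stop("no canonical residues in database")
  tab <- table(factor(aa, levels = aa_alphabet()))
  n <- as.numeric(tab)
  stats::setNames(n / sum(n), aa_alphabet())
}
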