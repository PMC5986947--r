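#' The canonical 20-letter amino acid alphabet
#'
#' Single-letter codes for the 20 standard amino acids in the fixed order
#' used throughout the package. This order defines the descriptor order of
#' every feature encoder: amino acid composition components, the row-major
#' enumeration of residue pairs in di-peptide and gap-pair compositions, and
#' the blocks of the composition-transition-distribution vector.
#'
#' @format Character vector of length 20:
#'   `A C D E F G H I K L M N P Q R S T V W Y`.
#' @export
#' @examples
#' AA_ALPHABET
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ordered labels of the 400 residue pairs (AA, AC, ..., YY), row-major.
aa_pair_labels <- function() {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
}

# Split a residue string into an integer vector of alphabet indices.
# Characters outside the alphabet map to NA.
residue_indices <- function(residues) {
  match(strsplit(residues, "", fixed = TRUE)[[1]], AA_ALPHABET)
}

#' The six essential nif gene categories
#'
#' Labels of the six nif gene products the multi-class stage distinguishes:
#' the structural nitrogenase components (nifH, nifD, nifK) and the
#' iron-molybdenum cofactor biosynthesis proteins (nifB, nifE, nifN).
#'
#' @format Character vector of length 6 in fixed order.
#' @export
NIF_CATEGORIES <- c("nifB", "nifD", "nifE", "nifH", "nifK", "nifN")
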