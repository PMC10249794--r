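# Oligonucleotide average masses.
#
# Neutral average mass of a 5'-OH DNA oligo: sum of per-base residue
# masses minus 61.96 Da (net H2O gain minus the missing 5'-phosphate).
# A dideoxynucleotide residue weighs 16.00 Da less than the
# deoxynucleotide residue (no 3'-oxygen). Only relative separations
# matter for allele assignment; terminator-chemistry mass tags of
# commercial cocktails are proprietary and not modelled.

DNA_RESIDUE_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
OLIGO_MASS_OFFSET <- -61.96
DD_RESIDUE_DELTA <- -16.00

#' Average neutral mass of a DNA oligonucleotide
#'
#' @param sequence non-degenerate DNA string (A/C/G/T).
#' @return mass in daltons.
#' @export
#' @examples
#' oligo_mass("CGCCGCGGCTCCCCT")
oligo_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  ch <- seq_chars(sequence)
  if (any(!(ch %in% DNA_BASES))) {
    stop("degenerate or invalid base in oligo: ",
         ch[which(!(ch %in% DNA_BASES))[1]], call. = FALSE)
  }
  sum(DNA_RESIDUE_MASS[ch]) + OLIGO_MASS_OFFSET
}

#' Mass increment of a dideoxynucleotide residue
#'
#' @param base terminator base (A/C/G/T).
#' @return residue mass in daltons.
#' @export
dd_residue_mass <- function(base) {
  stopifnot(base %in% DNA_BASES)
  unname(DNA_RESIDUE_MASS[base] + DD_RESIDUE_DELTA)
}

#' Mass of a single-base extension product
#'
#' Primer mass plus the dideoxy terminator residue for the physically
#' extended base (the base is taken literally; strand bookkeeping for
#' reverse-complement assays happens upstream).
#'
#' @param primer_seq non-degenerate primer sequence.
#' @param allele extended base (A/C/G/T).
#' @return mass in daltons.
#' @export
extension_product_mass <- function(primer_seq, allele) {
  oligo_mass(primer_seq) + dd_residue_mass(allele)
}
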