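#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @noRd
chars_seq <- function(ch) paste(ch, collapse = "")

#' Is a substitution a transition?
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' A<->G and C<->T; every other substitution is a transversion.
#'
#' @param from,to single upper-case bases.
#' @return logical.
#' @export
is_transition <- function(from, to) {
  (from %in% c("A", "G") & to %in% c("A", "G") & from != to) |
    (from %in% c("C", "T") & to %in% c("C", "T") & from != to)
}

#' @noRd
assert_bases <- function(x, what = "sequence", allow_n = TRUE) {
  ch <- seq_chars(x)
  ok <- if (allow_n) c(DNA_BASES, "N") else DNA_BASES
  bad <- which(!(ch %in% ok))
  if (length(bad) > 0) {
    stop(sprintf("invalid base '%s' in %s at position %d",
                 ch[bad[1]], what, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Path to a packaged fixture file
#'
#' @param ... path components under `inst/extdata`.
#' @return file path.
#' @export
snpms_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "snpms", mustWork = FALSE)
  if (identical(p, "")) stop("fixture not found: ",
                             file.path(...), call. = FALSE)
  p
}
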