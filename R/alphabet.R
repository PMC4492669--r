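#' @importFrom Biostrings readBStringSet
#' @importFrom ape read.tree write.tree collapse.singles
#' @importFrom optparse make_option OptionParser parse_args
#' @importFrom stats runif setNames
#' @importFrom utils head
NULL

#' Residue alphabets
#'
#' The classifier models sequences over a fixed, ordered residue alphabet
#' that always includes the gap character \code{"-"}: gaps are an ordinary
#' modeled character, so a deletion relative to the reference alignment
#' carries probability like any residue. \code{"DNA"} uses A, C, G, T plus
#' gap; \code{"Prot"} uses the 20 standard amino acids plus gap. The symbol
#' order is fixed and stored inside trained models.
#'
#' @param molecule \code{"DNA"} or \code{"Prot"}.
#' @return Character vector of single-character symbols, gap last.
#' @examples
#' moleculeAlphabet("DNA")
#' @export
moleculeAlphabet <- function(molecule) {
  molecule <- matchMolecule(molecule)
  if (molecule == "DNA") {
    c("A", "C", "G", "T", "-")
  } else {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  }
}

matchMolecule <- function(molecule) {
  if (!is.character(molecule) || length(molecule) != 1L ||
      !molecule %in% c("DNA", "Prot")) {
    stopUsage("molecule must be \"DNA\" or \"Prot\"")
  }
  molecule
}

#' Normalize a residue string
#'
#' Upper-cases the sequence and, for DNA, maps U to T (RNA input is accepted
#' transparently). Characters outside the alphabet (ambiguity codes such as
#' N or X) are retained: they are treated as unknowns and score at the
#' probability floor.
#'
#' @param x character vector of sequences.
#' @param molecule \code{"DNA"} or \code{"Prot"}.
#' @return Normalized character vector.
#' @export
normalizeSequence <- function(x, molecule) {
  molecule <- matchMolecule(molecule)
  x <- toupper(x)
  if (molecule == "DNA") x <- gsub("U", "T", x, fixed = TRUE)
  x
}

## Classed conditions so callers (and tests) can distinguish failure modes.
stopWith <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "pwmtreeError", "error", "condition"),
                 list(message = msg, call = NULL)))
}
stopFormat     <- function(msg) stopWith("pwmtreeFormatError", msg)
stopAlignment  <- function(msg) stopWith("pwmtreeAlignmentError", msg)
stopModelFormat<- function(msg) stopWith("pwmtreeModelFormatError", msg)
stopUsage      <- function(msg) stopWith("pwmtreeUsageError", msg)
stopValidation <- function(msg) stopWith("pwmtreeValidationError", msg)
stopInternal   <- function(msg) stopWith("pwmtreeInternalError", msg)
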