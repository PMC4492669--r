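## Henikoff position-based sequence weighting. Reduces over-sampling bias
## before PWM construction: identical or near-identical references share
## weight instead of piling it up. Applied once to the whole input
## alignment, never per clade.

seqMatrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' Henikoff position-based sequence weights
#'
#' For each alignment column, each of the r distinct residue types present
#' (the gap counts as a residue type) shares one unit of weight equally
#' among its s occurrences, so a sequence gains 1 / (r * s) from that
#' column. A sequence's raw weight is the sum over all columns; the raw
#' weights of an alignment therefore always sum to the number of columns.
#'
#' @param aln a [ReferenceAlignment-class].
#' @return Numeric vector of raw weights, one per record.
#' @references Henikoff S, Henikoff JG (1994) Position-based sequence
#'   weights. J Mol Biol 243:574-578.
#' @examples
#' aln <- readReferenceAlignment(text = c(
#'   ">s1 T1", "AA", ">s2 T2", "AC", ">s3 T3", "CC"), molecule = "DNA")
#' positionBasedWeights(aln)  # 0.75 0.50 0.75
#' @export
positionBasedWeights <- function(aln) {
  m <- seqMatrix(aln@seq)
  w <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    tab <- table(col)
    w <- w + 1 / (length(tab) * as.numeric(tab[col]))
  }
  w
}

#' Adjusted (integer) sequence weights
#'
#' Divides each raw weight by the smallest raw weight and rounds up to the
#' nearest integer, so no sequence has an adjusted weight below one. A tiny
#' tolerance guards against floating-point ratios that are mathematically
#' integral rounding up spuriously.
#'
#' @param raw positive numeric vector of raw weights.
#' @return Integer vector of adjusted weights (min is 1).
#' @export
adjustWeights <- function(raw) {
  if (any(raw <= 0)) stopInternal("raw weights must be positive")
  as.integer(ceiling(raw / min(raw) - 1e-9))
}

#' Expand an alignment to its weighted form
#'
#' Repeats each record so that its frequency in the expanded alignment
#' equals its adjusted weight. Record IDs and taxon labels are preserved.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param adjusted integer vector from [adjustWeights()], one per record.
#' @return The expanded [ReferenceAlignment-class] with
#'   \code{sum(adjusted)} records.
#' @export
expandAlignment <- function(aln, adjusted) {
  if (length(adjusted) != length(aln@seq))
    stopInternal("one adjusted weight per record required")
  idx <- rep(seq_along(aln@seq), times = adjusted)
  new("ReferenceAlignment", id = aln@id[idx], taxon = aln@taxon[idx],
      seq = aln@seq[idx], molecule = aln@molecule)
}
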