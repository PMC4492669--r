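## Position-specific weight matrices: per-column residue frequencies over
## the alphabet (gap included) and their integer-scaled log form.

#' Column residue frequencies
#'
#' Relative frequencies of the alphabet symbols in one alignment column.
#' Symbols outside the alphabet (unknowns such as N or X) are dropped from
#' the tally; unseen symbols get frequency 0 and are floored later, at
#' score conversion.
#'
#' @param residues character vector of single residues (one column).
#' @param alphabet ordered symbol set from [moleculeAlphabet()].
#' @return Named probability vector over \code{alphabet}.
#' @export
columnFrequencies <- function(residues, alphabet) {
  counts <- table(factor(residues, levels = alphabet))
  total <- sum(counts)
  if (total == 0) stopInternal("column contains no known symbols")
  as.numeric(counts) / total
}

#' Convert frequencies to integer log scores
#'
#' score(r) = floor(k * ln(max(f(r), epsilon))). The floor epsilon keeps
#' zero frequencies finite without perturbing observed frequencies; the
#' scale k keeps several decimal digits of log precision in integer
#' arithmetic (k = 1000 preserves 3).
#'
#' @param freqs numeric vector (or matrix) of probabilities in [0, 1].
#' @param k positive scale constant.
#' @param epsilon probability floor in (0, 1).
#' @return Integer scores, same shape as \code{freqs}; all <= 0.
#' @examples
#' freqToScores(0.5, k = 1000, epsilon = 1e-4)  # -694
#' @export
freqToScores <- function(freqs, k = 1000, epsilon = 1e-4) {
  if (k <= 0) stopUsage("k must be positive")
  if (epsilon <= 0 || epsilon >= 1) stopUsage("epsilon must lie in (0, 1)")
  out <- floor(k * log(pmax(freqs, epsilon)))
  storage.mode(out) <- "integer"
  out
}

pwmFromFreq <- function(freq, alphabet, k, epsilon) {
  rownames(freq) <- alphabet
  new("PWM", freq = freq, scores = freqToScores(freq, k, epsilon),
      alphabet = alphabet, k = k, epsilon = epsilon,
      floorScore = as.integer(floor(k * log(epsilon))))
}

#' Build a PWM from aligned sequences
#'
#' One frequency column per alignment position, converted to integer log
#' scores. Gap columns are modeled like any other: the PWM carries the
#' probability of a deletion with respect to the alignment.
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @param alphabet ordered symbol set.
#' @param k,epsilon see [freqToScores()].
#' @return A [PWM-class].
#' @export
buildPwm <- function(seqs, alphabet, k = 1000, epsilon = 1e-4) {
  if (length(seqs) < 1L) stopInternal("buildPwm needs at least one sequence")
  w <- nchar(seqs)
  if (any(w != w[1])) stopInternal("buildPwm needs equal-length sequences")
  m <- seqMatrix(seqs)
  freq <- vapply(seq_len(ncol(m)),
                 function(j) columnFrequencies(m[, j], alphabet),
                 numeric(length(alphabet)))
  freq <- matrix(freq, nrow = length(alphabet))
  pwmFromFreq(freq, alphabet, k, epsilon)
}

#' Average frequency matrices
#'
#' Unweighted arithmetic mean, cell by cell. Used to build inner-node PWMs
#' from their children, which equalizes sibling clades regardless of how
#' many sequences each contributes.
#'
#' @param freqs list of numeric matrices with identical dimensions.
#' @return The mean matrix; columns still sum to 1.
#' @export
averageFrequencyMatrices <- function(freqs) {
  if (length(freqs) < 1L) stopInternal("nothing to average")
  d <- dim(freqs[[1]])
  for (f in freqs)
    if (!identical(dim(f), d))
      stopInternal("frequency matrices differ in dimension")
  Reduce(`+`, freqs) / length(freqs)
}

#' Score an aligned sequence against a PWM
#'
#' Sum over positions of the integer score of the residue at that position.
#' The sequence must be exactly as long as the PWM (use [alignToPwm()]
#' first for raw queries). Symbols outside the alphabet contribute the
#' floor score, making them maximally uninformative but never fatal.
#'
#' @param pwm a [PWM-class].
#' @param s residue string of length \code{ncol(pwm@freq)}.
#' @return Integer total score (<= 0).
#' @export
scoreAligned <- function(pwm, s) {
  chars <- strsplit(s, "")[[1]]
  if (length(chars) != ncol(pwm@scores))
    stopUsage(sprintf("sequence length %d does not match PWM length %d",
                      length(chars), ncol(pwm@scores)))
  ridx <- match(chars, pwm@alphabet)
  known <- !is.na(ridx)
  total <- sum(pwm@scores[cbind(ridx[known], which(known))])
  total + as.numeric(pwm@floorScore) * sum(!known)
}

## Per-position match scores of a character vector against the PWM,
## unknowns at the floor. Internal helper for the aligner.
pwmMatchScores <- function(pwm, chars) {
  ridx <- match(chars, pwm@alphabet)
  out <- numeric(length(chars))
  known <- !is.na(ridx)
  ## one row per query char: scores of that char across all PWM positions
  out <- matrix(as.numeric(pwm@floorScore), nrow = length(chars),
                ncol = ncol(pwm@scores))
  if (any(known))
    out[known, ] <- pwm@scores[ridx[known], , drop = FALSE]
  out
}
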