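## Semi-global alignment of a raw query to the root PWM: global in the PWM
## (every PWM position is consumed exactly once, by a query residue or by
## the gap character) and local in the query (any query prefix/suffix may be
## skipped free; internal skips cost skipPenalty each). Dynamic programming
## in the Needleman-Wunsch family, but match scores come from the PWM and
## gaps are disallowed in the PWM.
##
## DP state M[i, j]: best score over alignments that consume PWM positions
## 1..i and query residues 1..j and have emitted at least one query residue
## (skipped prefix residues are free and enter via the constant "prefix"
## layer gapsum[i-1]). Scores are integer-valued throughout, so exact
## equality in doubles is safe for traceback. The internal-skip recurrence
## cur[j] = max(base[j], cur[j-1] + p) is computed as a vectorized
## max-plus scan: cur = p*j + cummax(base - p*j).

#' Align a raw query to a PWM
#'
#' Maximizes the summed score where placing query residue r at PWM position
#' i scores the PWM's score for r at i, emitting the gap character at i
#' scores the PWM's own gap column (deletions are modeled, not penalized ad
#' hoc), skipping query residues is free at either end of the query and
#' costs \code{skipPenalty} internally. The aligned query is exactly as
#' long as the PWM.
#'
#' @param pwm a [PWM-class] (in classification, the model root).
#' @param raw query residue string; gaps are stripped before alignment.
#' @param skipPenalty integer <= 0 charged per internally skipped query
#'   residue; default is the PWM floor score, which makes internal
#'   insertions possible but strongly discouraged.
#' @return The aligned query string (length = PWM length) with attribute
#'   \code{"score"}, the optimal total score.
#' @examples
#' pwm <- buildPwm(c("ACGT", "ACGT"), moleculeAlphabet("DNA"))
#' alignToPwm(pwm, "GACGT")  # leading G skipped free -> "ACGT"
#' @export
alignToPwm <- function(pwm, raw, skipPenalty = NULL) {
  q <- gsub("-", "", raw, fixed = TRUE)
  if (!nzchar(q)) stopUsage("query is empty after gap stripping")
  if (is.null(skipPenalty)) skipPenalty <- as.numeric(pwm@floorScore)
  if (skipPenalty > 0) stopUsage("skipPenalty must be <= 0")
  p <- as.numeric(skipPenalty)

  chars <- strsplit(q, "")[[1]]
  m <- length(chars)
  l <- ncol(pwm@scores)
  ms <- pwmMatchScores(pwm, chars)               # m x l
  gapIdx <- base::match("-", pwm@alphabet)
  gvec <- as.numeric(pwm@scores[gapIdx, ])
  gapsum <- c(0, cumsum(gvec))                   # gapsum[i + 1] = sum 1..i

  M <- matrix(-Inf, nrow = l + 1L, ncol = m + 1L)
  off <- p * seq_len(m)
  for (i in seq_len(l)) {
    prev <- M[i, ]                               # row i-1 (1-based storage)
    base <- pmax(pmax(prev[seq_len(m)], gapsum[i]) + ms[, i],
                 prev[-1L] + gvec[i])
    M[i + 1L, -1L] <- off + cummax(base - off)
  }

  ## Optimal end state: last emission at (i*, j*), suffix all gaps, trailing
  ## query skips free -- or no emission at all (all-gap alignment).
  tail <- M + (gapsum[l + 1L] - gapsum)          # recycles by column
  allGap <- gapsum[l + 1L]
  best <- max(tail)
  if (allGap >= best) {
    out <- strrep("-", l)
    attr(out, "score") <- allGap
    return(out)
  }
  hit <- which(tail == best, arr.ind = TRUE)
  ## deterministic end choice: earliest query residue, then latest PWM pos
  hit <- hit[order(hit[, 2L], -hit[, 1L]), , drop = FALSE]
  iEnd <- hit[1L, 1L] - 1L
  jEnd <- hit[1L, 2L] - 1L

  aligned <- rep("-", l)
  i <- iEnd; j <- jEnd
  repeat {
    cur <- M[i + 1L, j + 1L]
    fromPrefix <- gapsum[i]
    fromM <- M[i, j]                             # (i-1, j-1)
    if (cur == max(fromM, fromPrefix) + ms[j, i]) {
      aligned[i] <- chars[j]
      if (fromPrefix >= fromM) break             # prefix phase: done
      i <- i - 1L; j <- j - 1L
    } else if (cur == M[i, j + 1L] + gvec[i]) {
      i <- i - 1L
    } else if (j >= 1L && cur == M[i + 1L, j] + p) {
      j <- j - 1L
    } else {
      stopInternal("alignment traceback failed")
    }
  }
  out <- paste(aligned, collapse = "")
  attr(out, "score") <- best
  out
}

#' Align a query unless it is pre-aligned
#'
#' In pre-aligned mode the query is validated (its length must equal the
#' model's PWM length) and passed through unchanged; otherwise it is
#' aligned to the model's root PWM with [alignToPwm()].
#'
#' @param model a [ClassifierModel-class].
#' @param query residue string.
#' @param preAligned logical flag.
#' @param queryId used in error messages.
#' @return Aligned query string of length \code{modelLength(model)}.
#' @export
maybeAlign <- function(model, query, preAligned = FALSE, queryId = "query") {
  if (preAligned) {
    if (nchar(query) != model@refLength)
      stopUsage(sprintf(
        "pre-aligned query '%s' has length %d but the model expects %d",
        queryId, nchar(query), model@refLength))
    return(query)
  }
  alignToPwm(model@root$pwm, query)
}
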