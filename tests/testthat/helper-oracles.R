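# Independent oracles and tiny in-code fixtures shared across tests.

# Build a ReferenceAlignment from parallel vectors without going through
# FASTA text.
makeAln <- function(ids, taxa, seqs, molecule = "DNA") {
  readReferenceAlignment(
    text = as.vector(rbind(paste0(">", ids, " ", taxa), seqs)),
    molecule = molecule)
}

# Four-taxon, clearly separated DNA fixture used by several suites.
fourTaxonFixture <- function() {
  list(
    aln = makeAln(
      ids  = sprintf("r%02d", 1:12),
      taxa = rep(c("A", "B", "C", "D"), each = 3),
      seqs = c("AAAAAAAA", "AAAAAAAT", "AAAAAAAC",
               "CCCCCCCC", "CCCCCCCT", "CCCCCCCA",
               "GGGGGGGG", "GGGGGGGT", "GGGGGGGA",
               "TTTTTTTT", "TTTTTTTA", "TTTTTTTC")),
    tree = readTaxonTree(text = "((A,B)AB,(C,D)CD)Root;"))
}

# Henikoff position-based weights recomputed from first principles:
# explicit loop over columns and sequences, no shared code with the
# implementation's vectorized tally.
oracleHenikoff <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  w <- numeric(length(seqs))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    r <- length(unique(col))
    for (i in seq_along(col)) {
      s <- sum(col == col[i])
      w[i] <- w[i] + 1 / (r * s)
    }
  }
  w
}

# Exhaustive enumeration of every monotone alignment of a query (length m)
# to a PWM (length l): choose t matched positions in each, map in order;
# unmatched PWM positions emit the gap character; query residues skipped
# strictly between the first and last matched residues cost skipPenalty,
# end skips are free. Feasible for l, m <= 6.
oracleAlignScore <- function(pwm, query, skipPenalty = NULL) {
  if (is.null(skipPenalty)) skipPenalty <- as.numeric(pwm@floorScore)
  chars <- strsplit(query, "")[[1]]
  m <- length(chars)
  l <- ncol(pwm@scores)
  gapIdx <- match("-", pwm@alphabet)
  gapScore <- as.numeric(pwm@scores[gapIdx, ])
  symScore <- function(ch, pos) {
    i <- match(ch, pwm@alphabet)
    if (is.na(i)) as.numeric(pwm@floorScore) else as.numeric(pwm@scores[i, pos])
  }
  best <- sum(gapScore)  # t = 0: all gaps, whole query skipped free
  for (t in seq_len(min(l, m))) {
    pwmSets <- utils::combn(l, t)
    qrySets <- utils::combn(m, t)
    for (a in seq_len(ncol(pwmSets))) {
      ppos <- pwmSets[, a]
      gapPart <- sum(gapScore[-ppos])
      for (b in seq_len(ncol(qrySets))) {
        qpos <- qrySets[, b]
        matchPart <- sum(mapply(symScore, chars[qpos], ppos))
        internal <- (qpos[t] - qpos[1] + 1) - t
        total <- matchPart + gapPart + skipPenalty * internal
        if (total > best) best <- total
      }
    }
  }
  best
}

# Score a query against every leaf PWM of a model; argmax with first-in-
# model-order tie-break. The exhaustive counterpart of greedy descent.
exhaustiveLeafArgmax <- function(model, aligned) {
  leaves <- list()
  walk <- function(node) {
    if (length(node$children) == 0L) leaves[[length(leaves) + 1L]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(modelRoot(model))
  scores <- vapply(leaves, function(lf) scoreAligned(lf$pwm, aligned), 0)
  leaves[[which.max(scores)]]$label
}

# Random gapped DNA alignment for property tests.
randomAlignment <- function(n, l, gapProb = 0.15) {
  syms <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(syms, l, replace = TRUE)
    s[runif(l) < gapProb] <- "-"
    paste(s, collapse = "")
  }, "")
  makeAln(sprintf("s%03d", seq_len(n)), sprintf("t%03d", seq_len(n)), seqs)
}

# TRUE iff sub is a (possibly empty) subsequence of full.
isSubsequence <- function(sub, full) {
  if (!nzchar(sub)) return(TRUE)
  s <- strsplit(sub, "")[[1]]
  f <- strsplit(full, "")[[1]]
  j <- 1L
  for (ch in f) {
    if (j <= length(s) && ch == s[j]) j <- j + 1L
  }
  j > length(s)
}
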