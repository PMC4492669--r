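dna <- moleculeAlphabet("DNA")

test_that("column frequencies are counts over total, gap included", {
  expect_equal(columnFrequencies(c("A", "A", "C", "-"), dna),
               c(0.5, 0.25, 0, 0, 0.25))
  expect_equal(columnFrequencies(rep("A", 7), dna), c(1, 0, 0, 0, 0))
  expect_equal(columnFrequencies(c("A", "C", "G", "T", "-"), dna),
               rep(0.2, 5))
})

test_that("integer log scores match floor(k ln f) with an epsilon floor", {
  expect_equal(freqToScores(0.5, k = 1000, epsilon = 1e-4), -694L)
  expect_equal(freqToScores(1.0, k = 1000), 0L)
  expect_equal(freqToScores(0, k = 1000, epsilon = 1e-4), -9211L)

  # dense grid against direct evaluation (floor applied outside pmax)
  f <- seq(0, 1, length.out = 1000)
  eps <- 1e-4
  expected <- as.integer(floor(1000 * log(ifelse(f < eps, eps, f))))
  expect_identical(freqToScores(f, k = 1000, epsilon = eps), expected)
})

test_that("buildPwm tallies columns like an independent counting script", {
  p <- buildPwm(c("AA", "AC"), dna)
  expect_equal(p@freq[, 1], c(A = 1, C = 0, G = 0, T = 0, `-` = 0))
  expect_equal(p@freq[, 2], c(A = 0.5, C = 0.5, G = 0, T = 0, `-` = 0))

  oneHot <- buildPwm("AC-G", dna)
  expect_equal(unname(oneHot@freq["-", 3]), 1)
  expect_equal(diag(oneHot@freq[c("A", "C", "-", "G"), ]), rep(1, 4))

  seqs <- c("ACG-", "ACGT", "AC-T", "TCGT")
  p4 <- buildPwm(seqs, dna)
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (j in 1:4) {
    counts <- vapply(dna, function(s) sum(mat[, j] == s), 0)
    expect_equal(unname(p4@freq[, j]), unname(counts / 4))
  }
})

test_that("inner-node averaging is the unweighted cell mean", {
  a <- buildPwm("A", dna)@freq
  c_ <- buildPwm("C", dna)@freq
  expect_equal(averageFrequencyMatrices(list(a, c_))[, 1],
               c(A = 0.5, C = 0.5, G = 0, T = 0, `-` = 0))
  expect_equal(unname(averageFrequencyMatrices(list(a, a, c_))["A", 1]),
               2 / 3)
  expect_equal(averageFrequencyMatrices(list(a, a)), a)    # idempotent
  expect_error(averageFrequencyMatrices(list(a, buildPwm("AA", dna)@freq)),
               class = "pwmtreeInternalError")
  # averaged columns still sum to 1
  set.seed(42)
  ms <- lapply(1:3, function(i)
    buildPwm(alnSeqs(randomAlignment(3, 8)), dna)@freq)
  expect_true(all(abs(colSums(averageFrequencyMatrices(ms)) - 1) < 1e-9))
})

test_that("scoreAligned sums per-position scores, floor for unknowns", {
  expect_equal(scoreAligned(buildPwm("AC", dna), "AC"), 0)
  halves <- buildPwm(c("AC", "CA"), dna)
  expect_equal(scoreAligned(halves, "AC"), -1388)
  p <- buildPwm("AC", dna)
  expect_equal(scoreAligned(p, "NC"), p@floorScore + 0)
  expect_error(scoreAligned(p, "ACG"), class = "pwmtreeUsageError")

  # brute-force per-position sum on random instances
  set.seed(77)
  for (rep in 1:20) {
    l <- sample(1:12, 1)
    pw <- buildPwm(alnSeqs(randomAlignment(sample(1:5, 1), l)), dna)
    q <- paste(sample(c(dna, "N"), l, replace = TRUE), collapse = "")
    chars <- strsplit(q, "")[[1]]
    brute <- sum(vapply(seq_len(l), function(i) {
      r <- match(chars[i], pw@alphabet)
      if (is.na(r)) as.numeric(pw@floorScore) else pw@scores[r, i]
    }, 0))
    expect_equal(scoreAligned(pw, q), brute)
  }
})

test_that("raising a residue's frequency never lowers a matching score", {
  set.seed(88)
  for (rep in 1:20) {
    f <- as.numeric(columnFrequencies(sample(dna, 6, replace = TRUE), dna))
    r <- sample(5, 1)
    bump <- f
    bump[r] <- bump[r] + 0.3
    bump <- bump / sum(bump)
    if (bump[r] < f[r]) next
    expect_gte(freqToScores(bump, 1000)[r], freqToScores(f, 1000)[r])
  }
})

test_that("uniform matrices give the closed-form score", {
  l <- 9
  u <- matrix(1 / 5, nrow = 5, ncol = l)
  pw <- pwmtree:::pwmFromFreq(u, dna, k = 1000, epsilon = 1e-4)
  q <- paste(sample(dna[1:4], l, replace = TRUE), collapse = "")
  expect_equal(scoreAligned(pw, q), l * floor(1000 * log(1 / 5)))
})
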