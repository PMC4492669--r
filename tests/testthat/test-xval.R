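test_that("only taxa with enough sequences enter leave-one-out trials", {
  aln <- makeAln(sprintf("r%d", 1:4), c("X", "X", "X", "Y"),
                 c("AAAA", "AAAT", "AAAC", "CCCC"))
  expect_equal(suitableRecords(aln, 3), 1:3)
  two <- makeAln(sprintf("r%d", 1:4), c("X", "X", "Y", "Y"),
                 c("AAAA", "AAAT", "CCCC", "CCCA"))
  expect_length(suitableRecords(two, 3), 0)
  expect_equal(suitableRecords(two, 2), 1:4)
  expect_error(runLoocv(two, readTaxonTree(text = "(X,Y);"), minPerTaxon = 3),
               class = "pwmtreeValidationError")
})

test_that("LOOCV is error-free when taxa are trivially separable", {
  # 4 taxa x 5 identical-within, distinct-between sequences
  seqs <- rep(c(strrep("A", 30), strrep("C", 30),
                strrep("G", 30), strrep("T", 30)), each = 5)
  aln <- makeAln(sprintf("r%02d", 1:20), rep(c("A", "B", "C", "D"), each = 5),
                 seqs)
  tree <- readTaxonTree(text = "((A,B),(C,D));")
  res <- runLoocv(aln, tree, trials = 20, seed = 3)
  expect_equal(res@nTrials, 20L)
  expect_equal(res@nErrors, 0L)
  expect_equal(xvalErrorRate(res), 0)
})

test_that("trial count is capped by the number of suitable records", {
  fx <- evolveReferences(fixtureSpec(4, 5, 40, 0.02, 0.3, seed = 5))
  res <- runLoocv(fx$alignment, fx$tree, trials = 100, seed = 1)
  expect_equal(res@nTrials, 20L)            # every suitable sequence
})

test_that("identical seeds reproduce identical trial lists", {
  fx <- evolveReferences(fixtureSpec(4, 4, 50, 0.05, 0.25, seed = 6))
  a <- runLoocv(fx$alignment, fx$tree, trials = 8, seed = 99)
  b <- runLoocv(fx$alignment, fx$tree, trials = 8, seed = 99)
  expect_identical(xvalTrials(a), xvalTrials(b))
  c_ <- runLoocv(fx$alignment, fx$tree, trials = 8, seed = 100)
  expect_false(identical(xvalTrials(a)$recordId, xvalTrials(c_)$recordId))
})

test_that("error rate is invariant to record order when all records run", {
  fx <- evolveReferences(fixtureSpec(4, 4, 60, 0.08, 0.2, seed = 7))
  aln <- fx$alignment
  res <- runLoocv(aln, fx$tree, trials = 16, seed = 2)
  perm <- rev(seq_len(alnCount(aln)))
  alnPerm <- makeAln(alnIds(aln)[perm], alnTaxa(aln)[perm],
                     alnSeqs(aln)[perm])
  resPerm <- runLoocv(alnPerm, fx$tree, trials = 16, seed = 2)
  expect_equal(xvalErrorRate(resPerm), xvalErrorRate(res))
  # the same multiset of records was classified with the same outcomes
  a <- xvalTrials(res); b <- xvalTrials(resPerm)
  expect_identical(a[order(a$recordId), , drop = FALSE]$correct,
                   b[order(b$recordId), , drop = FALSE]$correct)
})

test_that("the withheld sequence never leaks into the trial model", {
  # withholding a compositionally unique sequence must change its taxon's
  # leaf matrix
  aln <- makeAln(sprintf("r%d", 1:4), rep("X", 4),
                 c("AAAA", "AAAA", "AAAA", "GGGG"))
  tree <- readTaxonTree(text = "(X,Y);")
  alnY <- makeAln(c(alnIds(aln), "y1", "y2", "y3"),
                  c(alnTaxa(aln), rep("Y", 3)),
                  c(alnSeqs(aln), rep("CCCC", 3)))
  full <- trainClassifier(alnY, tree)
  reduced <- trainClassifier(
    makeAln(alnIds(alnY)[-4], alnTaxa(alnY)[-4], alnSeqs(alnY)[-4]), tree)
  leafX <- function(m) {
    for (ch in modelRoot(m)$children) if (ch$label == "X") return(ch$pwm@freq)
  }
  expect_false(isTRUE(all.equal(leafX(full), leafX(reduced))))
  expect_equal(unname(leafX(reduced)["G", 1]), 0)   # no trace of the withheld seq
})

test_that("trial lines render as 'ID taxon<TAB>-> path'", {
  path <- new("ClassificationPath", queryId = "ZQBXK1",
              labels = c("Bacilli", "Bacillaceae", "Bacillus"),
              er = c(71, 101, 83), leafTaxon = "Bacillus",
              classified = TRUE, nScorings = 6L, score = 0)
  expect_identical(
    formatTrial("ZQBXK1", "Bacillus", path, correct = TRUE),
    "ZQBXK1 Bacillus\t-> Bacilli (71); Bacillaceae (101); Bacillus (83)")
  expect_null(formatTrial("ZQBXK1", "Bacillus", path, correct = TRUE,
                          wrongOnly = TRUE))
  expect_identical(
    formatTrial("ZQBXK1", "Bacillus", path, correct = FALSE,
                wrongOnly = TRUE),
    "ZQBXK1 Bacillus\t-> Bacilli (71); Bacillaceae (101); Bacillus (83)")
  res <- new("XvalResult",
             trials = data.frame(recordId = "a", trueTaxon = "X",
                                 predicted = "X", correct = TRUE),
             paths = list(path), nTrials = 1L, nErrors = 0L,
             errorRate = 0, seed = 1L)
  expect_identical(formatXvalSummary(res), "trials 1, errors 0, error rate 0%")
})
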