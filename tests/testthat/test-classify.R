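test_that("evidence ratios convert score gaps to rounded log10 units", {
  expect_equal(evidenceRatioLog10(-500, -500, k = 1000), 0)
  expect_equal(evidenceRatioLog10(0, -2303, k = 1000), 1)
  expect_equal(evidenceRatioLog10(0, -163484, k = 1000), 71)
  expect_identical(evidenceRatioLog10(-10, -Inf, k = 1000), Inf)
  expect_error(evidenceRatioLog10(-10, 0, k = 1000),
               class = "pwmtreeInternalError")
})

test_that("greedy descent picks the right leaf with positive confidence", {
  aln <- makeAln(sprintf("r%d", 1:4), c("A", "A", "B", "B"),
                 c("AAAA", "AAAA", "CCCC", "CCCC"))
  model <- trainClassifier(aln, readTaxonTree(text = "(A,B);"))
  path <- descend(model, maybeAlign(model, "AAAA", preAligned = TRUE))
  expect_equal(predictedTaxon(path), "A")
  expect_length(pathER(path), 1)
  expect_gt(pathER(path), 0)
})

test_that("scoring count follows the 2-per-level rule in balanced trees", {
  fx <- fourTaxonFixture()
  model <- trainClassifier(fx$aln, fx$tree)
  path <- descend(model, maybeAlign(model, "AAAAAAAA", preAligned = TRUE))
  expect_equal(path@nScorings, 4L)          # 2 children x 2 levels

  # depth-3 balanced tree over 8 taxa: exactly 6 scorings
  fx8 <- evolveReferences(fixtureSpec(8, 2, 60, 0, 0.3, seed = 9))
  m8 <- trainClassifier(fx8$alignment, fx8$tree)
  p8 <- descend(m8, maybeAlign(m8, fx8$heldOut$seq[1]))
  expect_equal(p8@nScorings, 2L * treeDepth(fx8$tree))
  expect_equal(treeDepth(fx8$tree), 3L)
})

test_that("tied children resolve to the first in model order with ER 0", {
  fx <- evolveReferences(fixturePreset("tie"))
  model <- trainClassifier(fx$alignment, fx$tree)
  path <- descend(model, maybeAlign(model, fx$heldOut$seq[2]))
  expect_equal(predictedTaxon(path), modelTaxa(model)[1])
  expect_equal(pathER(path), 0)
})

test_that("the cutoff rule rejects paths with any weak decision", {
  mkPath <- function(ers) new("ClassificationPath", queryId = "q",
                              labels = sprintf("L%d", seq_along(ers)),
                              er = ers, leafTaxon = sprintf("L%d", length(ers)),
                              classified = TRUE, nScorings = 0L, score = 0)
  expect_false(applyCutoff(mkPath(c(132, 21, 9)), 10)@classified)
  expect_true(applyCutoff(mkPath(c(132, 21, 9)), 0)@classified)
  expect_true(applyCutoff(mkPath(c(116, 163, 153)), 10)@classified)
  # infinite steps never fail the cutoff
  expect_true(applyCutoff(mkPath(c(116, Inf, 153)), 10)@classified)
})

test_that("result lines match the published layout byte for byte", {
  path <- new("ClassificationPath", queryId = "A0RIG4_BACAH",
              labels = c("Bacilli", "Bacillaceae", "Bacillus"),
              er = c(71, 101, 83), leafTaxon = "Bacillus",
              classified = TRUE, nScorings = 6L, score = 0)
  expect_identical(
    formatResult("A0RIG4_BACAH", path),
    "A0RIG4_BACAH\t-> Bacilli (71); Bacillaceae (101); Bacillus (83)")

  star <- new("ClassificationPath", queryId = "q",
              labels = c("Clostridia", "Clostridiales", "Clostridium"),
              er = c(132, Inf, 9), leafTaxon = "Clostridium",
              classified = TRUE, nScorings = 6L, score = 0)
  expect_identical(
    formatResult("A5Z6L5_9FIRM", star),
    "A5Z6L5_9FIRM\t-> Clostridia (132); Clostridiales (*); Clostridium (9)")

  unnamed <- new("ClassificationPath", queryId = "q",
                 labels = c("", "X"), er = c(1500, 3), leafTaxon = "X",
                 classified = TRUE, nScorings = 4L, score = 0)
  expect_identical(formatResult("q", unnamed), "q\t-> unnamed (*); X (3)")
})

test_that("result lines round-trip through the provided parser", {
  parsed <- parseResultLine(
    "A5Z6L5_9FIRM\t-> Clostridia (132); Clostridiales (*); Clostridium (9)")
  expect_equal(parsed$id, "A5Z6L5_9FIRM")
  expect_equal(parsed$labels,
               c("Clostridia", "Clostridiales", "Clostridium"))
  expect_equal(parsed$er, c(132, Inf, 9))
  expect_false(parsed$unclassified)
  expect_true(parseResultLine("q\t-> A (3)\tUNCLASSIFIED")$unclassified)
})

test_that("classifySequences preserves order and flags weak queries", {
  fx <- evolveReferences(fixturePreset("easy"))
  model <- trainClassifier(fx$alignment, fx$tree)
  qs <- fx$heldOut[1:3, c("id", "seq")]
  lines <- classifySequences(model, qs)
  expect_length(lines, 3)
  expect_equal(vapply(lines, function(l) parseResultLine(l)$id, ""),
               qs$id, ignore_attr = TRUE)

  empty <- classifySequences(model, fx$heldOut[0, c("id", "seq")])
  expect_length(empty, 0)

  # cutoff flags agree with recomputed per-step evidence ratios
  cutoff <- 10
  lines10 <- classifySequences(model, fx$heldOut[, c("id", "seq")],
                               erCutoff = cutoff)
  paths <- attr(lines10, "paths")
  for (i in seq_along(lines10)) {
    ers <- pathER(paths[[i]])
    weak <- any(ers[is.finite(ers)] < cutoff)
    expect_identical(parseResultLine(lines10[i])$unclassified, weak)
  }
})

test_that("greedy descent matches exhaustive leaf argmax on easy data", {
  agree <- 0L; total <- 0L
  for (seed in 1:2) {
    fx <- evolveReferences(fixturePreset("easy", seed = seed))
    model <- trainClassifier(fx$alignment, fx$tree)
    for (i in seq_len(nrow(fx$heldOut))) {
      aligned <- maybeAlign(model, fx$heldOut$seq[i])
      greedy <- predictedTaxon(descend(model, aligned))
      total <- total + 1L
      if (identical(greedy, exhaustiveLeafArgmax(model, aligned)))
        agree <- agree + 1L
    }
  }
  expect_gte(agree / total, 0.99)
})
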