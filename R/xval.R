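## Leave-one-out cross-validation: withhold one reference sequence, retrain
## on the rest (weighting recomputed on the reduced alignment), classify
## the withheld sequence raw, and tally errors.

#' Records suitable for leave-one-out trials
#'
#' A withheld sequence can only be classified correctly if its taxon is
#' still represented in the classifier, so only taxa with at least
#' \code{minPerTaxon} sequences (default 3) take part.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param minPerTaxon minimum sequences a taxon needs to contribute trials.
#' @return Integer vector of record indices.
#' @export
suitableRecords <- function(aln, minPerTaxon = 3) {
  counts <- table(aln@taxon)
  ok <- names(counts)[counts >= minPerTaxon]
  which(aln@taxon %in% ok)
}

#' Leave-one-out cross-validation
#'
#' Draws records at random without replacement among the suitable ones,
#' and for each: trains a fresh classifier on the alignment minus that one
#' record (tree unchanged, Henikoff weighting recomputed), strips the
#' withheld sequence's gaps, aligns and classifies it, and scores the
#' prediction as correct iff the predicted leaf equals the record's taxon.
#' The error count divided by the number of trials estimates the
#' classifier's error rate.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param tree an \pkg{ape} \code{phylo}.
#' @param k,epsilon,innerMode passed to [trainClassifier()].
#' @param trials requested number of trials; the effective number is
#'   \code{min(trials, number of suitable records)} (default 100, or every
#'   suitable sequence when fewer).
#' @param minPerTaxon see [suitableRecords()].
#' @param seed integer driving record sampling; identical seeds give
#'   identical trial lists.
#' @return An [XvalResult-class].
#' @export
runLoocv <- function(aln, tree, k = 1000, epsilon = 1e-4,
                     innerMode = "child_average", trials = 100,
                     minPerTaxon = 3, seed = 1) {
  suitable <- suitableRecords(aln, minPerTaxon)
  if (length(suitable) == 0L)
    stopValidation(sprintf(
      "no taxon has >= %d reference sequences; cross-validation impossible",
      minPerTaxon))
  nTrials <- min(trials, length(suitable))
  picked <- withSeed(seed, sample(suitable, nTrials, replace = FALSE))

  results <- data.frame(recordId = character(nTrials),
                        trueTaxon = character(nTrials),
                        predicted = character(nTrials),
                        correct = logical(nTrials),
                        stringsAsFactors = FALSE)
  paths <- vector("list", nTrials)
  for (t in seq_len(nTrials)) {
    idx <- picked[t]
    reduced <- new("ReferenceAlignment", id = aln@id[-idx],
                   taxon = aln@taxon[-idx], seq = aln@seq[-idx],
                   molecule = aln@molecule)
    model <- suppressWarnings(
      trainClassifier(reduced, tree, k = k, epsilon = epsilon,
                      innerMode = innerMode))
    aligned <- maybeAlign(model, aln@seq[idx], preAligned = FALSE,
                          queryId = aln@id[idx])
    path <- descend(model, aligned, queryId = aln@id[idx])
    results$recordId[t] <- aln@id[idx]
    results$trueTaxon[t] <- aln@taxon[idx]
    results$predicted[t] <- path@leafTaxon
    results$correct[t] <- identical(path@leafTaxon, aln@taxon[idx])
    paths[[t]] <- path
  }
  nErrors <- sum(!results$correct)
  new("XvalResult", trials = results, paths = paths,
      nTrials = as.integer(nTrials), nErrors = as.integer(nErrors),
      errorRate = nErrors / nTrials, seed = as.integer(seed))
}

#' Format one cross-validation trial
#'
#' \code{"ID taxon<TAB>-> path"} in the same path notation as
#' [formatResult()]; returns \code{NULL} for correct trials when
#' \code{wrongOnly} is set.
#'
#' @param recordId,trueTaxon identity of the withheld record.
#' @param path the trial's [ClassificationPath-class].
#' @param correct logical.
#' @param wrongOnly print only wrong classifications.
#' @return Character line or \code{NULL}.
#' @export
formatTrial <- function(recordId, trueTaxon, path, correct,
                        wrongOnly = FALSE) {
  if (wrongOnly && correct) return(NULL)
  formatResult(paste(recordId, trueTaxon), path)
}

#' Format the cross-validation summary line
#'
#' @param x an [XvalResult-class].
#' @return Character line, e.g. \code{"trials 60, errors 0, error rate 0%"}.
#' @export
formatXvalSummary <- function(x) {
  sprintf("trials %d, errors %d, error rate %g%%",
          x@nTrials, x@nErrors, 100 * x@errorRate)
}

## Run code under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
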