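## Model training: validate alignment/tree consistency, weight the
## alignment, then build a PWM at every node of the taxon tree, bottom-up.

#' Validate alignment and phylogeny for training
#'
#' Checks that every tree leaf has at least one reference sequence and that
#' every alignment taxon appears in the tree (both fatal), and flags taxa
#' represented by a single sequence (warning: such taxa cannot take part in
#' leave-one-out cross-validation).
#'
#' @param aln a [ReferenceAlignment-class].
#' @param tree an \pkg{ape} \code{phylo} from [readTaxonTree()].
#' @return list with character vectors \code{fatal} and \code{warnings};
#'   valid input yields \code{length(fatal) == 0}.
#' @export
validateInputs <- function(aln, tree) {
  fatal <- character()
  warnings <- character()
  counts <- table(aln@taxon)
  leafless <- setdiff(tree$tip.label, names(counts))
  if (length(leafless))
    fatal <- c(fatal, sprintf(
      "tree leaf '%s' has no sequences in the alignment", leafless))
  orphan <- setdiff(names(counts), tree$tip.label)
  if (length(orphan))
    fatal <- c(fatal, sprintf(
      "alignment taxon '%s' is not a leaf of the tree", orphan))
  singles <- names(counts)[counts == 1]
  singles <- setdiff(singles, orphan)
  if (length(singles))
    warnings <- c(warnings, sprintf(
      "taxon '%s' has only one reference sequence", singles))
  list(fatal = fatal, warnings = warnings)
}

#' Train a classifier model
#'
#' Pipeline: Henikoff position-based weights on the whole alignment ->
#' integer adjusted weights -> weighted (expanded) alignment -> one
#' frequency matrix per leaf taxon -> inner-node matrices bottom-up ->
#' every frequency matrix converted to an integer score matrix.
#'
#' Inner-node matrices are, by default, the unweighted mean of the node's
#' child matrices (\code{innerMode = "child_average"}), which gives sibling
#' clades equal say regardless of sampling depth. With
#' \code{innerMode = "clade_pooled"} an inner matrix is instead computed by
#' pooling all (weighted) sequences of the clade; the two coincide when
#' every child contributes the same number of sequences.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param tree an \pkg{ape} \code{phylo}; leaf labels must match the
#'   alignment's taxa.
#' @param k,epsilon scoring constants, see [freqToScores()].
#' @param innerMode \code{"child_average"} (default) or
#'   \code{"clade_pooled"}.
#' @return A [ClassifierModel-class].
#' @examples
#' aln <- readReferenceAlignment(text = c(
#'   ">r1 A", "AAAA", ">r2 A", "AAAA", ">r3 B", "CCCC", ">r4 B", "CCCC"),
#'   molecule = "DNA")
#' tree <- readTaxonTree(text = "(A,B)Root;")
#' model <- trainClassifier(aln, tree)
#' modelTaxa(model)
#' @export
trainClassifier <- function(aln, tree, k = 1000, epsilon = 1e-4,
                            innerMode = c("child_average", "clade_pooled")) {
  innerMode <- match.arg(innerMode)
  report <- validateInputs(aln, tree)
  for (w in report$warnings) warning(w, call. = FALSE)
  if (length(report$fatal))
    stopValidation(paste(c("training input validation failed:",
                           report$fatal), collapse = "\n  "))

  alphabet <- moleculeAlphabet(aln@molecule)
  raw <- positionBasedWeights(aln)
  expanded <- expandAlignment(aln, adjustWeights(raw))
  byTaxon <- split(expanded@seq, expanded@taxon)

  ntip <- length(tree$tip.label)
  rootNum <- ntip + 1L

  buildNode <- function(v) {
    label <- phyloNodeLabel(tree, v)
    if (v <= ntip) {
      seqs <- byTaxon[[label]]
      return(list(label = label,
                  pwm = buildPwm(seqs, alphabet, k, epsilon),
                  seqs = seqs, children = list()))
    }
    children <- lapply(phyloChildren(tree, v), buildNode)
    freq <- if (innerMode == "child_average") {
      averageFrequencyMatrices(lapply(children, function(ch) ch$pwm@freq))
    } else {
      buildPwm(unlist(lapply(children, `[[`, "seqs"), use.names = FALSE),
               alphabet, k, epsilon)@freq
    }
    list(label = label, pwm = pwmFromFreq(freq, alphabet, k, epsilon),
         seqs = unlist(lapply(children, `[[`, "seqs"), use.names = FALSE),
         children = children)
  }

  root <- if (ntip == 1L) buildNode(1L) else buildNode(rootNum)
  root <- stripSeqs(root)
  new("ClassifierModel", root = root, molecule = aln@molecule,
      alphabet = alphabet, k = k, epsilon = epsilon,
      refLength = as.integer(alnLength(aln)), nLeaves = as.integer(ntip),
      innerMode = innerMode, version = MODEL_FORMAT_VERSION)
}

## Pooled sequences are scaffolding for clade_pooled construction; they do
## not belong in the stored model.
stripSeqs <- function(node) {
  node$seqs <- NULL
  node$children <- lapply(node$children, stripSeqs)
  node
}
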