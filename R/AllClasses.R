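#' @import methods
NULL

#' Reference multiple alignment
#'
#' A gapped multiple alignment of reference sequences, each carrying a record
#' ID and the name of the taxon it represents. This is the training input:
#' taxon labels connect alignment records to the leaves of the reference
#' phylogeny.
#'
#' @slot id character, one record ID per sequence (non-empty).
#' @slot taxon character, one taxon name per sequence (non-empty).
#' @slot seq character, aligned sequences of identical length, which may
#'   contain the gap character \code{"-"}.
#' @slot molecule \code{"DNA"} or \code{"Prot"}.
#' @export
setClass("ReferenceAlignment",
  representation(id = "character", taxon = "character", seq = "character",
                 molecule = "character"),
  validity = function(object) {
    n <- length(object@seq)
    if (n < 1L) return("alignment must contain at least one record")
    if (length(object@id) != n || length(object@taxon) != n)
      return("id, taxon and seq must have equal length")
    if (any(!nzchar(object@id))) return("record IDs must be non-empty")
    if (any(!nzchar(object@taxon))) return("taxon names must be non-empty")
    w <- nchar(object@seq)
    if (w[1] < 1L) return("sequences must be non-empty")
    if (any(w != w[1])) {
      bad <- object@id[which(w != w[1])[1]]
      return(sprintf("unequal sequence lengths (record '%s')", bad))
    }
    TRUE
  })

#' Position-specific weight matrix
#'
#' Per-position residue frequencies over the alphabet (gap included) together
#' with their integer-scaled log-probability form: the score of symbol r at
#' position i is floor(k * ln(max(f_i(r), epsilon))). Integer scores make
#' sequence scoring a fast exact sum; \code{floorScore} is the score assigned
#' to zero-frequency and unknown symbols.
#'
#' @slot freq numeric matrix, symbols x positions; every column sums to 1.
#' @slot scores integer matrix, same shape; entries are <= 0.
#' @slot alphabet ordered symbol set (gap included).
#' @slot k positive scale constant applied to the natural log.
#' @slot epsilon probability floor in (0, 1) applied inside the log.
#' @slot floorScore integer, floor(k * ln(epsilon)).
#' @export
setClass("PWM",
  representation(freq = "matrix", scores = "matrix", alphabet = "character",
                 k = "numeric", epsilon = "numeric", floorScore = "integer"),
  validity = function(object) {
    if (!identical(dim(object@freq), dim(object@scores)))
      return("freq and scores must have identical dimensions")
    if (nrow(object@freq) != length(object@alphabet))
      return("one matrix row per alphabet symbol required")
    if (object@k <= 0) return("k must be positive")
    if (object@epsilon <= 0 || object@epsilon >= 1)
      return("epsilon must lie in (0, 1)")
    cs <- colSums(object@freq)
    if (length(cs) && any(abs(cs - 1) > 1e-9))
      return("frequency columns must sum to 1")
    if (any(object@freq < 0 | object@freq > 1))
      return("frequencies must lie in [0, 1]")
    if (any(object@scores > 0L)) return("scores must be <= 0")
    TRUE
  })

#' Trained classifier model
#'
#' A tree of PWMs with the same topology as the reference phylogeny: a leaf
#' matrix models one reference taxon, an inner matrix models the clade below
#' it. The root PWM is used once per query for semi-global alignment; greedy
#' descent then compares the aligned query against sibling matrices only.
#'
#' The tree is stored as a recursive node list; use [modelRoot()],
#' [modelLength()], [modelTaxa()] and friends rather than reaching into
#' slots.
#'
#' @slot root recursive node list (label, pwm, children).
#' @slot molecule \code{"DNA"} or \code{"Prot"}.
#' @slot alphabet ordered symbol set.
#' @slot k,epsilon scoring constants shared by every PWM in the tree.
#' @slot refLength alignment length (PWM positions).
#' @slot nLeaves number of reference taxa.
#' @slot innerMode \code{"child_average"} or \code{"clade_pooled"}.
#' @slot version model format version.
#' @export
setClass("ClassifierModel",
  representation(root = "list", molecule = "character", alphabet = "character",
                 k = "numeric", epsilon = "numeric", refLength = "integer",
                 nLeaves = "integer", innerMode = "character",
                 version = "integer"),
  validity = function(object) {
    if (!object@molecule %in% c("DNA", "Prot"))
      return("molecule must be \"DNA\" or \"Prot\"")
    if (object@refLength < 1L) return("refLength must be >= 1")
    if (object@nLeaves < 1L) return("model must contain at least one taxon")
    if (!object@innerMode %in% c("child_average", "clade_pooled"))
      return("unknown innerMode")
    ok <- checkNode(object@root, object@refLength, object@alphabet)
    if (!isTRUE(ok)) return(ok)
    TRUE
  })

checkNode <- function(node, l, alphabet) {
  if (!is(node$pwm, "PWM")) return("every node must carry a PWM")
  if (ncol(node$pwm@freq) != l) return("all PWMs must span the full alignment")
  if (!identical(node$pwm@alphabet, alphabet))
    return("all PWMs must share the model alphabet")
  for (child in node$children) {
    ok <- checkNode(child, l, alphabet)
    if (!isTRUE(ok)) return(ok)
  }
  TRUE
}

#' Classification path
#'
#' The result of one greedy descent: the chosen node labels from just below
#' the root down to a leaf taxon, with the rounded log10 evidence ratio of
#' each decision (best-scoring child vs next-best; \code{Inf} when the node
#' has a single child and no next-best exists).
#'
#' @slot queryId ID of the classified query.
#' @slot labels node labels along the path (\code{""} for unlabeled nodes).
#' @slot er non-negative log10 evidence ratios (may contain \code{Inf}).
#' @slot leafTaxon the predicted reference taxon (last label on the path).
#' @slot classified logical flag under the active evidence-ratio cutoff.
#' @slot nScorings how many child matrices were scored during the descent.
#' @slot score integer alignment score of the query at the winning leaf.
#' @export
setClass("ClassificationPath",
  representation(queryId = "character", labels = "character", er = "numeric",
                 leafTaxon = "character", classified = "logical",
                 nScorings = "integer", score = "numeric"),
  validity = function(object) {
    if (length(object@labels) != length(object@er))
      return("labels and er must have equal length")
    if (any(object@er < 0)) return("evidence ratios must be non-negative")
    if (length(object@labels) &&
        !identical(object@leafTaxon, object@labels[length(object@labels)]))
      return("leafTaxon must equal the last path label")
    TRUE
  })

#' Leave-one-out cross-validation result
#'
#' @slot trials data.frame with one row per trial: recordId, trueTaxon,
#'   predicted, correct.
#' @slot paths list of [ClassificationPath-class] objects, one per trial.
#' @slot nTrials,nErrors counts.
#' @slot errorRate nErrors / nTrials.
#' @slot seed the seed that drove record sampling.
#' @export
setClass("XvalResult",
  representation(trials = "data.frame", paths = "list", nTrials = "integer",
                 nErrors = "integer", errorRate = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@errorRate < 0 || object@errorRate > 1)
      return("errorRate must lie in [0, 1]")
    if (nrow(object@trials) != object@nTrials)
      return("trial table and nTrials disagree")
    TRUE
  })

setMethod("show", "ReferenceAlignment", function(object) {
  cat(sprintf("ReferenceAlignment: %d sequences x %d positions (%s), %d taxa\n",
              length(object@seq), nchar(object@seq[1]), object@molecule,
              length(unique(object@taxon))))
})

setMethod("show", "PWM", function(object) {
  cat(sprintf("PWM: %d positions over {%s}, k = %g, epsilon = %g\n",
              ncol(object@freq), paste(object@alphabet, collapse = ""),
              object@k, object@epsilon))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel (%s): %d taxa, %d positions, k = %g, epsilon = %g, %s\n",
    object@molecule, object@nLeaves, object@refLength, object@k,
    object@epsilon, object@innerMode))
})

setMethod("show", "ClassificationPath", function(object) {
  cat(formatResult(object@queryId, object), "\n")
})

setMethod("show", "XvalResult", function(object) {
  cat(sprintf("LOOCV: trials %d, errors %d, error rate %.2f%%\n",
              object@nTrials, object@nErrors, 100 * object@errorRate))
})

#' @describeIn ReferenceAlignment-class record IDs.
#' @param x,object a \code{ReferenceAlignment}.
#' @export
alnIds <- function(x) x@id

#' @describeIn ReferenceAlignment-class taxon label per record.
#' @export
alnTaxa <- function(x) x@taxon

#' @describeIn ReferenceAlignment-class aligned sequences.
#' @export
alnSeqs <- function(x) x@seq

#' @describeIn ReferenceAlignment-class number of alignment columns.
#' @export
alnLength <- function(x) nchar(x@seq[1])

#' @describeIn ReferenceAlignment-class number of records.
#' @export
alnCount <- function(x) length(x@seq)

#' @describeIn ClassifierModel-class root node of the PWM tree.
#' @export
modelRoot <- function(x) x@root

#' @describeIn ClassifierModel-class alignment length (PWM positions).
#' @export
modelLength <- function(x) x@refLength

#' @describeIn ClassifierModel-class molecule type.
#' @export
modelMolecule <- function(x) x@molecule

#' @describeIn ClassifierModel-class leaf taxon labels, in model order.
#' @export
modelTaxa <- function(x) {
  collect <- function(node) {
    if (length(node$children) == 0L) return(node$label)
    unlist(lapply(node$children, collect), use.names = FALSE)
  }
  collect(x@root)
}

#' @describeIn ClassificationPath-class labels along the path.
#' @param path a \code{ClassificationPath}.
#' @export
pathLabels <- function(path) path@labels

#' @describeIn ClassificationPath-class log10 evidence ratios along the path.
#' @export
pathER <- function(path) path@er

#' @describeIn ClassificationPath-class predicted leaf taxon.
#' @export
predictedTaxon <- function(path) path@leafTaxon

#' @describeIn XvalResult-class per-trial table.
#' @param x an \code{XvalResult}.
#' @export
xvalTrials <- function(x) x@trials

#' @describeIn XvalResult-class estimated error rate.
#' @export
xvalErrorRate <- function(x) x@errorRate
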