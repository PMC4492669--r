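## Greedy descent through the PWM tree with evidence-ratio confidence.
## The aligned query is scored against the children of the current node,
## the best child is chosen, and the log10 evidence ratio against the
## next-best sibling is recorded; recursion stops at a leaf. In a balanced
## fully bifurcating tree of n taxa this scores only ~2*log2(n) matrices
## instead of n.

#' Log10 evidence ratio between two scores
#'
#' Scores are k-scaled natural-log probabilities, so the likelihood ratio
#' between the best and next-best matrix is exp((best - next) / k) and its
#' log10 is (best - next) / (k * ln 10), reported rounded to an integer.
#' A node with a single child has no next-best; \code{Inf} is returned.
#'
#' @param best,next_ integer scores with \code{best >= next_}.
#' @param k the model's scale constant.
#' @return Non-negative integer (or \code{Inf}).
#' @examples
#' evidenceRatioLog10(0, -2303, k = 1000)  # 1
#' @export
evidenceRatioLog10 <- function(best, next_, k) {
  if (is.infinite(next_)) return(Inf)
  if (best < next_) stopInternal("evidence ratio requires best >= next")
  round((best - next_) / (k * log(10)))
}

#' Greedy descent through the PWM tree
#'
#' @param model a [ClassifierModel-class].
#' @param aligned aligned query string of length \code{modelLength(model)}
#'   (from [maybeAlign()]).
#' @param queryId ID recorded on the returned path.
#' @return A [ClassificationPath-class]: chosen labels from just below the
#'   root down to a leaf, one log10 evidence ratio per decision (ties go to
#'   the first child in model order, with ER 0), and the number of child
#'   matrices scored.
#' @export
descend <- function(model, aligned, queryId = "query") {
  if (nchar(aligned) != model@refLength)
    stopUsage("aligned query length does not match the model")
  node <- model@root
  labels <- character()
  ers <- numeric()
  nScorings <- 0L
  score <- scoreAligned(node$pwm, aligned)
  while (length(node$children) > 0L) {
    scores <- vapply(node$children,
                     function(ch) scoreAligned(ch$pwm, aligned), 0)
    nScorings <- nScorings + length(scores)
    bestIdx <- which.max(scores)               # ties -> first child
    nextBest <- if (length(scores) > 1L) max(scores[-bestIdx]) else -Inf
    node <- node$children[[bestIdx]]
    labels <- c(labels, node$label)
    ers <- c(ers, evidenceRatioLog10(scores[bestIdx], nextBest, model@k))
    score <- scores[bestIdx]
  }
  new("ClassificationPath", queryId = queryId, labels = labels, er = ers,
      leafTaxon = if (length(labels)) labels[length(labels)] else node$label,
      classified = TRUE, nScorings = nScorings, score = score)
}

#' Apply an evidence-ratio cutoff
#'
#' A query counts as classified only if every finite decision on its path
#' has log10 evidence ratio at or above the cutoff; one weak decision
#' anywhere makes the whole assignment unreliable. Cutoff 0 classifies
#' everything.
#'
#' @param path a [ClassificationPath-class].
#' @param erCutoff non-negative integer.
#' @return The path with its \code{classified} flag set.
#' @export
applyCutoff <- function(path, erCutoff = 0) {
  if (erCutoff < 0) stopUsage("erCutoff must be >= 0")
  finite <- path@er[is.finite(path@er)]
  path@classified <- all(finite >= erCutoff)
  path
}

renderER <- function(er) {
  ifelse(is.infinite(er) | er > 1000, "*", as.character(er))
}

#' Format a classification result line
#'
#' One TAB-separated line per query:
#' \code{"ID<TAB>-> label1 (er1); label2 (er2); ..."}. An unlabeled node
#' appears as \code{unnamed}; an evidence ratio above 1000 (or a decision
#' with no alternative) is rendered as \code{*}.
#'
#' @param queryId query ID.
#' @param path a [ClassificationPath-class].
#' @return Single character line.
#' @export
formatResult <- function(queryId, path) {
  labels <- ifelse(nzchar(path@labels), path@labels, "unnamed")
  steps <- sprintf("%s (%s)", labels, renderER(path@er))
  paste0(queryId, "\t-> ", paste(steps, collapse = "; "))
}

#' Classify a set of queries
#'
#' Aligns (unless pre-aligned) and classifies each query in input order.
#' Under a positive cutoff, queries failing the evidence-ratio rule are
#' still printed, flagged with a final \code{UNCLASSIFIED} column.
#'
#' @param model a [ClassifierModel-class].
#' @param queries data.frame from [readQueries()] (columns \code{id},
#'   \code{seq}).
#' @param preAligned treat queries as already aligned to the model.
#' @param erCutoff non-negative evidence-ratio cutoff (0 = no cutoff).
#' @return Character vector of output lines, one per query, with the
#'   corresponding [ClassificationPath-class] list as attribute
#'   \code{"paths"}.
#' @export
classifySequences <- function(model, queries, preAligned = FALSE,
                              erCutoff = 0) {
  if (nrow(queries) == 0L) {
    out <- character()
    attr(out, "paths") <- list()
    return(out)
  }
  checkMoleculeHeuristic(model, queries$seq)
  paths <- vector("list", nrow(queries))
  lines <- character(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    aligned <- maybeAlign(model, queries$seq[i], preAligned,
                          queryId = queries$id[i])
    path <- applyCutoff(descend(model, aligned, queries$id[i]), erCutoff)
    lines[i] <- formatResult(queries$id[i], path)
    if (erCutoff > 0 && !path@classified)
      lines[i] <- paste0(lines[i], "\tUNCLASSIFIED")
    paths[[i]] <- path
  }
  attr(lines, "paths") <- paths
  lines
}

## Cheap residue heuristic: protein queries against a DNA model (or vice
## versa) deserve a warning, not an error.
checkMoleculeHeuristic <- function(model, seqs) {
  probe <- toupper(paste(utils::head(seqs, 10), collapse = ""))
  probe <- gsub("-", "", probe, fixed = TRUE)
  if (!nzchar(probe)) return(invisible())
  acgt <- nchar(gsub("[^ACGTU]", "", probe))
  frac <- acgt / nchar(probe)
  if (model@molecule == "DNA" && frac < 0.5)
    warning("queries look like protein but the model is DNA", call. = FALSE)
  if (model@molecule == "Prot" && frac > 0.99)
    warning("queries look like DNA but the model is protein", call. = FALSE)
  invisible()
}

#' Parse a classification result line
#'
#' Inverse of [formatResult()]: recovers the query ID, path labels and
#' evidence ratios (\code{Inf} for \code{"*"}) and the UNCLASSIFIED flag
#' from one output line.
#'
#' @param line a line produced by [formatResult()] / [classifySequences()].
#' @return list with \code{id}, \code{labels}, \code{er},
#'   \code{unclassified}.
#' @export
parseResultLine <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L || !startsWith(parts[2], "-> "))
    stopFormat("not a classification result line")
  steps <- strsplit(sub("^-> ", "", parts[2]), "; ", fixed = TRUE)[[1]]
  m <- regmatches(steps, regexec("^(.*) \\(([0-9]+|\\*)\\)$", steps))
  if (any(vapply(m, length, 0L) != 3L))
    stopFormat("malformed path step in result line")
  list(id = parts[1],
       labels = vapply(m, `[`, "", 2L),
       er = vapply(m, function(x) if (x[3] == "*") Inf else as.numeric(x[3]),
                   0),
       unclassified = length(parts) > 2L && parts[3] == "UNCLASSIFIED")
}
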