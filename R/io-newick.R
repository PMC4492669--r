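## Newick I/O. Parsing is delegated to ape; this layer owns validation:
## balanced parentheses with a position diagnostic, terminating ';', unique
## leaf labels, collapsing single-child chains. Branch lengths and support
## values are parsed and discarded -- the classifier uses topology and
## labels only.

checkNewickSyntax <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stopFormat(sprintf("Newick parse error: unmatched ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stopFormat(sprintf(
      "Newick parse error: %d unclosed '(' at end of input", depth))
  if (!grepl(";", s, fixed = TRUE))
    stopFormat("Newick parse error: missing terminating ';'")
}

#' Read a reference phylogeny
#'
#' Reads a rooted Newick tree of the reference taxa. Leaf labels must match
#' the taxon names used in the reference alignment; inner-node labels (clade
#' names) are optional but recommended, as they make the classification path
#' more informative. Branch lengths, if present, are ignored. Single-child
#' chains are collapsed so that every internal node has at least two
#' children.
#'
#' @param file path to a Newick file (single statement ending in \code{;}).
#' @param text optional Newick string used instead of \code{file}.
#' @return An \pkg{ape} \code{phylo} object (taxon tree).
#' @examples
#' tr <- readTaxonTree(text =
#'   "((Bacillus,Paenibacillus)Bacillaceae,(Clostridium,(Butyrivibrio,
#'    Marvinbryantia)Lachnospiraceae)Clostridiales)Firmicutes;")
#' tr$tip.label
#' @export
readTaxonTree <- function(file, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(file)) stopUsage(sprintf("file not found: %s", file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  } else {
    text <- paste(text, collapse = "")
  }
  checkNewickSyntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stopFormat(sprintf("Newick parse error: %s",
                                           conditionMessage(e))),
    warning = function(w) stopFormat(sprintf("Newick parse error: %s",
                                             conditionMessage(w))))
  if (is.null(tree)) stopFormat("Newick parse error: no tree found")
  tree <- ape::collapse.singles(tree)
  tree$edge.length <- NULL
  if (anyDuplicated(tree$tip.label))
    stopValidation(sprintf(
      "duplicate leaf labels: %s",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
            collapse = ", ")))
  tree
}

#' Write a phylogeny in Newick format
#'
#' @param tree an \pkg{ape} \code{phylo} object.
#' @param file output path.
#' @export
writeTaxonTree <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

## Children of internal node 'v', in edge order (ape preserves the order in
## which clades appear in the Newick string); this order fixes downstream
## tie-breaking.
phyloChildren <- function(tree, v) {
  tree$edge[tree$edge[, 1] == v, 2]
}

phyloNodeLabel <- function(tree, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(tree$tip.label[v])
  if (is.null(tree$node.label)) return("")
  lab <- tree$node.label[v - ntip]
  if (is.na(lab)) "" else lab
}
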