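## Deterministic synthetic reference sets: a balanced taxon tree and
## clade-structured sequence families with controlled within-taxon and
## between-clade divergence. Everything downstream (training, alignment,
## descent, cross-validation) is testable on these without any downloads.

#' Specify a synthetic reference set
#'
#' @param nTaxa number of reference taxa (>= 1).
#' @param seqsPerTaxon reference sequences per taxon (one extra per taxon is
#'   generated and withheld as a held-out query).
#' @param length alignment length before gap columns are applied.
#' @param withinDivergence per-site substitution probability between a
#'   taxon's ancestral sequence and each of its sequences.
#' @param betweenDivergence per-site substitution probability applied along
#'   each tree edge.
#' @param gapProb per-site probability that a column becomes a shared gap
#'   column within a taxon (exercises gap-as-character machinery).
#' @param molecule \code{"DNA"} or \code{"Prot"}.
#' @param seed integer; the whole set is a deterministic function of the
#'   spec including this seed.
#' @return A \code{FixtureSpec} (validated list).
#' @export
fixtureSpec <- function(nTaxa, seqsPerTaxon, length, withinDivergence,
                        betweenDivergence, gapProb = 0, molecule = "DNA",
                        seed = 1) {
  molecule <- matchMolecule(molecule)
  probs <- c(withinDivergence, betweenDivergence, gapProb)
  if (any(probs < 0 | probs > 1))
    stopUsage("divergence and gap probabilities must lie in [0, 1]")
  if (nTaxa < 1 || seqsPerTaxon < 1 || length < 1)
    stopUsage("counts must be >= 1")
  structure(list(nTaxa = as.integer(nTaxa),
                 seqsPerTaxon = as.integer(seqsPerTaxon),
                 length = as.integer(length),
                 withinDivergence = withinDivergence,
                 betweenDivergence = betweenDivergence,
                 gapProb = gapProb, molecule = molecule,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Named fixture presets
#'
#' \code{"easy"}: 10 taxa x 6 sequences, length 300, within-taxon
#' divergence 0.02, between-clade divergence 0.25 per edge -- taxa are far
#' apart relative to within-taxon noise, so a sound classifier should make
#' essentially no cross-validation errors. \code{"hard"}: same sizes with
#' within 0.10 and between 0.12, where greedy descent is allowed to
#' disagree with exhaustive search. \code{"tie"}: two taxa with identical
#' sequence families, forcing tied scores and exercising the deterministic
#' first-child tie-break (ER 0).
#'
#' @param name \code{"easy"}, \code{"hard"} or \code{"tie"}.
#' @param seed overrides the preset's seed.
#' @return A \code{FixtureSpec}.
#' @export
fixturePreset <- function(name, seed = 1) {
  switch(name,
    easy = fixtureSpec(10, 6, 300, 0.02, 0.25, gapProb = 0.02, seed = seed),
    hard = fixtureSpec(10, 6, 300, 0.10, 0.12, gapProb = 0.02, seed = seed),
    tie  = fixtureSpec(2, 4, 100, 0, 0, gapProb = 0, seed = seed),
    stopUsage(sprintf("unknown preset '%s'", name)))
}

#' Balanced fully bifurcating taxon tree
#'
#' Leaves are labeled T001, T002, ...; an inner node is labeled by the
#' first and last leaf of its clade (e.g. \code{T001_T004}), so every label
#' is unique. The tree splits each clade as evenly as possible, giving
#' depth \code{ceiling(log2(nTaxa))}.
#'
#' @param nTaxa number of leaves (>= 2).
#' @return An \pkg{ape} \code{phylo}.
#' @export
randomBalancedTree <- function(nTaxa) {
  if (nTaxa < 2) stopUsage("a tree needs at least 2 taxa")
  width <- max(3L, nchar(as.character(nTaxa)))
  leaf <- function(i) sprintf("T%0*d", width, i)
  build <- function(lo, hi) {
    if (lo == hi) return(leaf(lo))
    mid <- lo + ceiling((hi - lo + 1L) / 2L) - 1L
    sprintf("(%s,%s)%s_%s", build(lo, mid), build(mid + 1L, hi),
            leaf(lo), leaf(hi))
  }
  readTaxonTree(text = paste0(build(1L, nTaxa), ";"))
}

#' Topological depth of a tree
#'
#' Maximum number of edges from the root to any leaf.
#'
#' @param tree an \pkg{ape} \code{phylo}.
#' @return Integer depth.
#' @export
treeDepth <- function(tree) {
  max(leafDepths(tree))
}

#' Per-leaf topological depths
#'
#' @param tree an \pkg{ape} \code{phylo}.
#' @return Named integer vector, edges from root to each leaf.
#' @export
leafDepths <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- integer(ntip + tree$Nnode)
  ## edges are listed parent-before-child from the root in ape's ordering
  for (r in seq_len(nrow(tree$edge)))
    depth[tree$edge[r, 2]] <- depth[tree$edge[r, 1]] + 1L
  stats::setNames(depth[seq_len(ntip)], tree$tip.label)
}

mutateSeq <- function(chars, p, symbols) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    alt <- symbols[symbols != chars[i]]
    chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

#' Evolve a synthetic reference set along a taxon tree
#'
#' A random root sequence is mutated along each tree edge with per-site
#' probability \code{betweenDivergence} (uniform replacement among the
#' other symbols, Jukes-Cantor style); each taxon's ancestral sequence then
#' spawns \code{seqsPerTaxon} reference copies plus one withheld query,
#' each mutated with \code{withinDivergence}. Per-taxon shared gap columns
#' are applied with probability \code{gapProb}. The result is a
#' deterministic function of the spec.
#'
#' @param tree an \pkg{ape} \code{phylo} whose leaves name the taxa; by
#'   default a balanced tree over \code{spec$nTaxa} leaves.
#' @param spec a \code{FixtureSpec} from [fixtureSpec()] or
#'   [fixturePreset()].
#' @return list with \code{alignment} (a [ReferenceAlignment-class]),
#'   \code{tree}, and \code{heldOut} (data.frame id/seq/taxon, one withheld
#'   query per taxon, never part of the alignment).
#' @export
evolveReferences <- function(spec, tree = NULL) {
  if (!inherits(spec, "FixtureSpec")) stopUsage("spec must be a FixtureSpec")
  if (is.null(tree)) tree <- randomBalancedTree(spec$nTaxa)
  symbols <- setdiff(moleculeAlphabet(spec$molecule), "-")
  withSeed(spec$seed, {
    rootSeq <- symbols[sample.int(length(symbols), spec$length,
                                  replace = TRUE)]
    ntip <- length(tree$tip.label)
    ancestral <- vector("list", ntip + tree$Nnode)
    rootNum <- if (ntip == 1L) 1L else ntip + 1L
    ancestral[[rootNum]] <- rootSeq
    for (r in seq_len(nrow(tree$edge))) {
      par <- tree$edge[r, 1]; child <- tree$edge[r, 2]
      ancestral[[child]] <- mutateSeq(ancestral[[par]],
                                      spec$betweenDivergence, symbols)
    }
    ids <- taxa <- seqs <- character()
    hIds <- hTaxa <- hSeqs <- character()
    for (tip in seq_len(ntip)) {
      taxon <- tree$tip.label[tip]
      anc <- ancestral[[tip]]
      gapCols <- which(stats::runif(spec$length) < spec$gapProb)
      fam <- vapply(seq_len(spec$seqsPerTaxon + 1L), function(i) {
        s <- mutateSeq(anc, spec$withinDivergence, symbols)
        s[gapCols] <- "-"
        paste(s, collapse = "")
      }, "")
      ids <- c(ids, sprintf("%ss%d", taxon, seq_len(spec$seqsPerTaxon)))
      taxa <- c(taxa, rep(taxon, spec$seqsPerTaxon))
      seqs <- c(seqs, fam[seq_len(spec$seqsPerTaxon)])
      hIds <- c(hIds, sprintf("%sq", taxon))
      hTaxa <- c(hTaxa, taxon)
      hSeqs <- c(hSeqs, fam[spec$seqsPerTaxon + 1L])
    }
    list(alignment = new("ReferenceAlignment", id = ids, taxon = taxa,
                         seq = seqs, molecule = spec$molecule),
         tree = tree,
         heldOut = data.frame(id = hIds, seq = hSeqs, taxon = hTaxa,
                              stringsAsFactors = FALSE))
  })
}

#' Write a fixture set to a directory
#'
#' Emits \code{alignment.fasta} (reference-header dialect),
#' \code{tree.nw} and \code{queries.fasta} (held-out sequences).
#'
#' @param fx result of [evolveReferences()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFixtureSet <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeReferenceFasta(fx$alignment, file.path(dir, "alignment.fasta"))
  writeTaxonTree(fx$tree, file.path(dir, "tree.nw"))
  writeQueryFasta(fx$heldOut, file.path(dir, "queries.fasta"))
  invisible(dir)
}
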