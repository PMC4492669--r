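## FASTA I/O. Parsing proper is delegated to Biostrings; this layer owns the
## reference-header dialect ("ID taxon"), normalization and validation.

readFastaRaw <- function(file, text = NULL) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  if (!file.exists(file)) stopUsage(sprintf("file not found: %s", file))
  set <- tryCatch(Biostrings::readBStringSet(file),
                  error = function(e)
                    stopFormat(sprintf("cannot parse FASTA '%s': %s",
                                       file, conditionMessage(e))))
  if (length(set) == 0L) stopFormat(sprintf("empty FASTA file: %s", file))
  list(header = names(set), seq = unname(as.character(set)))
}

#' Read a reference multiple alignment
#'
#' Reads a gapped FASTA multiple alignment whose headers carry a record ID
#' followed by the taxon name, separated by white space, e.g.
#' \code{">AAJGZX Clostridium"}. Sequences are upper-cased and, for DNA, U is
#' mapped to T. Only the second header token is used as the taxon name;
#' taxon names containing spaces are not supported.
#'
#' @param file path to a FASTA file.
#' @param molecule \code{"DNA"} or \code{"Prot"}.
#' @param text optional character vector of FASTA lines, used instead of
#'   \code{file} (convenient for small in-memory alignments).
#' @return A [ReferenceAlignment-class].
#' @examples
#' aln <- readReferenceAlignment(text = c(
#'   ">AAJGZX Clostridium",  "ACTGCTG----GTA",
#'   ">AB67CH Butyrivibrio", "ACTTGCC----GCA"), molecule = "DNA")
#' alnTaxa(aln)
#' @export
readReferenceAlignment <- function(file, molecule, text = NULL) {
  molecule <- matchMolecule(molecule)
  raw <- readFastaRaw(file, text)
  toks <- strsplit(trimws(raw$header), "[[:space:]]+")
  nt <- vapply(toks, length, 0L)
  if (any(nt < 2L)) {
    bad <- raw$header[which(nt < 2L)[1]]
    stopFormat(sprintf(
      "reference header must be 'ID taxon' (>= 2 tokens): '>%s'", bad))
  }
  id <- vapply(toks, `[`, "", 1L)
  taxon <- vapply(toks, `[`, "", 2L)
  if (anyDuplicated(id))
    warning(sprintf("duplicate record IDs: %s",
                    paste(unique(id[duplicated(id)]), collapse = ", ")))
  seqs <- normalizeSequence(raw$seq, molecule)
  if (any(!nzchar(seqs))) {
    bad <- id[which(!nzchar(seqs))[1]]
    stopFormat(sprintf("record '%s' has no sequence", bad))
  }
  w <- nchar(seqs)
  if (any(w != w[1])) {
    bad <- id[which(w != w[1])[1]]
    stopAlignment(sprintf(
      "unequal sequence lengths: record '%s' has %d columns, expected %d",
      bad, w[which(w != w[1])[1]], w[1]))
  }
  new("ReferenceAlignment", id = id, taxon = taxon, seq = seqs,
      molecule = molecule)
}

#' Read query sequences
#'
#' Reads a FASTA file of queries to classify (usually unaligned; gaps, if
#' present, are only meaningful in pre-aligned mode). The query ID is the
#' first whitespace-separated header token.
#'
#' @inheritParams readReferenceAlignment
#' @return data.frame with columns \code{id} and \code{seq}, input order
#'   preserved.
#' @export
readQueries <- function(file, molecule = "DNA", text = NULL) {
  molecule <- matchMolecule(molecule)
  raw <- readFastaRaw(file, text)
  id <- vapply(strsplit(trimws(raw$header), "[[:space:]]+"), `[`, "", 1L)
  if (any(!nzchar(id))) stopFormat("query header with empty ID")
  seqs <- normalizeSequence(raw$seq, molecule)
  if (any(!nzchar(seqs))) {
    bad <- id[which(!nzchar(seqs))[1]]
    stopFormat(sprintf("query '%s' has no sequence", bad))
  }
  data.frame(id = id, seq = seqs, stringsAsFactors = FALSE)
}

#' Write a reference alignment as gapped FASTA
#'
#' Inverse of [readReferenceAlignment()]: headers are \code{">ID taxon"}.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param file output path.
#' @export
writeReferenceFasta <- function(aln, file) {
  lines <- as.vector(rbind(paste0(">", aln@id, " ", aln@taxon), aln@seq))
  writeLines(lines, file)
  invisible(file)
}

#' Write query sequences as FASTA
#'
#' @param queries data.frame with columns \code{id} and \code{seq}.
#' @param file output path.
#' @export
writeQueryFasta <- function(queries, file) {
  lines <- as.vector(rbind(paste0(">", queries$id), queries$seq))
  writeLines(lines, file)
  invisible(file)
}
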