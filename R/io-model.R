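## Binary model container.
##
## Byte layout (all integers unsigned 32-bit, big-endian):
##   bytes 1-4   magic "PWTC"
##   bytes 5-8   container format version (currently 1)
##   bytes 9-12  payload length in bytes
##   bytes 13-   payload: R serialization (format 2) of the model fields,
##               including every integer score matrix bit-for-bit.
## The magic and version make incompatible files fail fast instead of
## deserializing garbage.

MODEL_MAGIC <- charToRaw("PWTC")
MODEL_FORMAT_VERSION <- 1L

#' Save a trained classifier model
#'
#' Writes the model to a versioned binary container (see the package source
#' for the byte layout). The round trip \code{loadModel(saveModel(m))} is
#' exact: every frequency and every integer score is restored bit-for-bit.
#'
#' @param model a [ClassifierModel-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, file) {
  if (!is(model, "ClassifierModel"))
    stopUsage("saveModel expects a ClassifierModel")
  payload <- serialize(
    list(root = model@root, molecule = model@molecule,
         alphabet = model@alphabet, k = model@k, epsilon = model@epsilon,
         refLength = model@refLength, nLeaves = model@nLeaves,
         innerMode = model@innerMode, version = model@version),
    connection = NULL, version = 2)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(MODEL_MAGIC, con)
  writeBin(MODEL_FORMAT_VERSION, con, size = 4L, endian = "big")
  writeBin(length(payload), con, size = 4L, endian = "big")
  writeBin(payload, con)
  invisible(file)
}

#' Load a classifier model
#'
#' @param file path to a file written by [saveModel()].
#' @return The restored [ClassifierModel-class].
#' @export
loadModel <- function(file) {
  if (!file.exists(file)) stopUsage(sprintf("file not found: %s", file))
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, MODEL_MAGIC))
    stopModelFormat(sprintf("'%s' is not a pwmtree model (bad magic bytes)",
                            file))
  ver <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(ver) != 1L || ver != MODEL_FORMAT_VERSION)
    stopModelFormat(sprintf(
      "unsupported model container version %s (this build reads version %d)",
      if (length(ver)) ver else "<missing>", MODEL_FORMAT_VERSION))
  len <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(len) != 1L || is.na(len) || len <= 0L)
    stopModelFormat(sprintf("truncated model file: %s", file))
  payload <- readBin(con, "raw", n = len)
  if (length(payload) != len)
    stopModelFormat(sprintf(
      "truncated model file: expected %d payload bytes, found %d",
      len, length(payload)))
  fields <- tryCatch(unserialize(payload),
                     error = function(e)
                       stopModelFormat(sprintf("corrupt model payload: %s",
                                               conditionMessage(e))))
  new("ClassifierModel", root = fields$root, molecule = fields$molecule,
      alphabet = fields$alphabet, k = fields$k, epsilon = fields$epsilon,
      refLength = fields$refLength, nLeaves = fields$nLeaves,
      innerMode = fields$innerMode, version = fields$version)
}
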