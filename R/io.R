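## Plain-text / PNG interchange for images, tensors and rosters.

#' Read and write ECG printout images
#'
#' PNG round trip for [EcgImage-class] objects (pixels stored 0..255).
#'
#' @param image An [EcgImage-class].
#' @param path PNG file path.
#' @param layout Layout to attach on read.
#' @param sourceId Source identifier to attach on read.
#' @return `writeEcgImage` the path invisibly; `readEcgImage` an
#'   [EcgImage-class].
#' @export
writeEcgImage <- function(image, path) {
  stopifnot(is(image, "EcgImage"))
  png::writePNG(imagePixels(image) / 255, path)
  invisible(path)
}

#' @rdname writeEcgImage
#' @export
readEcgImage <- function(path, layout = standardLeadLayout(),
                         sourceId = basename(path)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  new("EcgImage", pixels = array(as.integer(round(px * 255)),
                                 dim = dim(px)),
      layout = layout, sourceId = sourceId)
}

#' Write a signal tensor as CSV
#'
#' One column per lead, one row per sample (1250 rows at the defaults);
#' the extracted rhythm strip, when present, is written alongside with the
#' suffix `_rhythm.csv`.
#'
#' @param tensor A [SignalTensor-class].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writeSignalTensor <- function(tensor, path) {
  stopifnot(is(tensor, "SignalTensor"))
  write.csv(as.data.frame(tensorValues(tensor)), path, row.names = FALSE)
  rhythm <- attr(tensorValues(tensor), "rhythm")
  if (!is.null(rhythm))
    write.csv(data.frame(rhythm_II = rhythm),
              sub("\\.csv$", "_rhythm.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignalTensor
#' @param rateHz,durationS Sampling metadata to attach on read.
#' @export
readSignalTensor <- function(path, rateHz = 500, durationS = 2.5) {
  vals <- as.matrix(utils::read.csv(path, check.names = FALSE))
  colnames(vals) <- colnames(vals)
  new("SignalTensor", values = vals, rateHz = rateHz, durationS = durationS)
}
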