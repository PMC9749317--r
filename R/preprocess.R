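## Image preprocessing: red-grid removal, cropping, binarization/inversion,
## and resizing to the 2-D model input.

#' Remove the red grid background
#'
#' Sets every red-dominant pixel (R - max(G, B) above `redThreshold`) to
#' background white and converts the remainder to grayscale with standard
#' luma weights (0.299, 0.587, 0.114). Dark trace ink fails the red
#' predicate and is retained. Grayscale input is returned as-is (nothing is
#' red-dominant), which makes the operation idempotent.
#'
#' @param image An [EcgImage-class], an H x W x 3 array (0..255), or a
#'   grayscale H x W matrix.
#' @param redThreshold Red-dominance threshold (default 30).
#' @return Grayscale H x W numeric matrix with values in 0..255.
#' @export
removeGrid <- function(image, redThreshold = 30) {
  px <- if (is(image, "EcgImage")) imagePixels(image) else image
  if (is.matrix(px)) return(px)  # already grayscale: predicate matches nothing
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  red <- px[, , 1] - pmax(px[, , 2], px[, , 3])
  g <- rgbToLuma(px)
  isGrid <- red > redThreshold
  if (all(isGrid)) warnf("image is entirely red-dominant; result is blank")
  g[isGrid] <- 255
  g
}

#' Crop to the signal content
#'
#' Tight bounding box of the non-background (darker than
#' `backgroundThreshold`) content, expanded by `marginPx` and clipped to
#' the image bounds. The crop position is recorded in the `"cropOffset"`
#' attribute (1-based row, col of the crop's top-left corner).
#'
#' @param gray Grayscale matrix (0..255).
#' @param marginPx Margin to add around the bounding box.
#' @param backgroundThreshold Pixels at or above this intensity count as
#'   background (default 250).
#' @return The cropped matrix with attribute `cropOffset`.
#' @export
cropToSignal <- function(gray, marginPx = 2L, backgroundThreshold = 250) {
  stopifnot(is.matrix(gray))
  idx <- which(gray < backgroundThreshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("no signal content to crop to")
  r1 <- max(1L, min(idx[, 1]) - marginPx)
  r2 <- min(nrow(gray), max(idx[, 1]) + marginPx)
  c1 <- max(1L, min(idx[, 2]) - marginPx)
  c2 <- min(ncol(gray), max(idx[, 2]) + marginPx)
  out <- gray[r1:r2, c1:c2, drop = FALSE]
  attr(out, "cropOffset") <- c(as.integer(r1), as.integer(c1))
  out
}

#' Binarize and invert to an ink mask
#'
#' Pixels darker than `inkThreshold` become foreground 255, all others
#' background 0 (intensity inversion followed by a hard threshold).
#'
#' @param gray Grayscale matrix (0..255), typically the output of
#'   [cropToSignal()]; its `cropOffset` attribute, if present, is carried
#'   into the mask.
#' @param inkThreshold Intensity below which a pixel is ink (default 128).
#' @return A [TraceMask-class].
#' @export
binarizeInvert <- function(gray, inkThreshold = 128) {
  stopifnot(is.matrix(gray))
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[gray < inkThreshold] <- 255L
  off <- attr(gray, "cropOffset")
  if (is.null(off)) off <- c(1L, 1L)
  new("TraceMask", pixels = m, cropOffset = as.integer(off))
}

## Bilinear sampling plan for one axis: source neighbour indices and the
## fractional weight of the lower neighbour, pixel-center convention
## (exact identity when sizes match).
bilinearAxis <- function(nIn, nOut) {
  x <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  x <- pmin(pmax(x, 0), nIn - 1)
  i0 <- pmin(floor(x), nIn - 1)
  list(i0 = as.integer(i0) + 1L,
       i1 = as.integer(pmin(i0 + 1, nIn - 1)) + 1L,
       w = x - i0)
}

#' Resize to the 2-D model input
#'
#' Bilinear resize (pixel-center convention, separable, vectorized) to
#' exactly 512 (width) x 256 (height) x 3 channels, scaled to [0, 1]. An
#' input already at the target size passes through unchanged up to scaling.
#'
#' @param image An [EcgImage-class], an H x W x 3 array (0..255), or a
#'   grayscale matrix (replicated across channels).
#' @param width,height Target size (defaults 512 x 256).
#' @return Numeric array of dim (height, width, 3) with values in [0, 1].
#' @export
resizeForImageModel <- function(image, width = 512L, height = 256L) {
  px <- if (is(image, "EcgImage")) imagePixels(image) else image
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  px <- px / 255
  if (dim(px)[1] == height && dim(px)[2] == width) return(px)
  rv <- bilinearAxis(dim(px)[1], height)
  cv <- bilinearAxis(dim(px)[2], width)
  w00 <- (1 - rv$w) %o% (1 - cv$w); w10 <- rv$w %o% (1 - cv$w)
  w01 <- (1 - rv$w) %o% cv$w;       w11 <- rv$w %o% cv$w
  out <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) {
    pl <- px[, , ch]
    out[, , ch] <- w00 * pl[rv$i0, cv$i0] + w10 * pl[rv$i1, cv$i0] +
                   w01 * pl[rv$i0, cv$i1] + w11 * pl[rv$i1, cv$i1]
  }
  out
}
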