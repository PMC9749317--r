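#' @import methods
#' @importFrom stats approx rnorm runif setNames quantile cor
#' @importFrom utils head tail write.csv
NULL

## Run code with a temporary RNG seed, restoring the caller's RNG state.
## All user-facing randomness in the package flows through this helper so
## that no function leaves hidden global state behind.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## ITU-R BT.601 luma weights; the conventional grayscale conversion.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

## Collapse an H x W x 3 array (0..255) to grayscale H x W (0..255).
rgbToLuma <- function(px) {
  LUMA_WEIGHTS[1] * px[, , 1] + LUMA_WEIGHTS[2] * px[, , 2] +
    LUMA_WEIGHTS[3] * px[, , 3]
}

clampInt <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Canonical 12-lead order used throughout the package.
LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")
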