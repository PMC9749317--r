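## Trace extraction: sub-image splitting, pixel-column scanning,
## nearest-trace grouping, and lead assembly.

#' Split a trace mask into the four sub-images
#'
#' With a layout, boundaries come from the layout geometry (translated by
#' the mask's crop offset) and every slice is padded to exactly
#' `columnsPerSubimage` columns so column indices stay aligned with time.
#' Without a layout, boundaries are detected from blank-column valleys in
#' the ink density; a mask without three interior valleys but with a width
#' divisible by four is split into equal quarters.
#'
#' @param mask A [TraceMask-class].
#' @param layout A [LeadLayout-class], or NULL to detect boundaries.
#' @return List of `nSubimages` binary matrices (values {0, 255}).
#' @export
splitSubimages <- function(mask, layout = NULL) {
  px <- maskPixels(mask)
  if (ncol(px) < 4L) stopf("mask is too narrow to split (%d cols)", ncol(px))
  if (!is.null(layout)) {
    nc <- layout@columnsPerSubimage
    offC <- cropOffset(mask)[2]
    subs <- vector("list", layout@nSubimages)
    for (q in seq_len(layout@nSubimages)) {
      sub <- matrix(0L, nrow(px), nc)
      orig <- (q - 1L) * nc + seq_len(nc)       # columns in image coords
      here <- orig - offC + 1L                  # columns in mask coords
      keep <- here >= 1L & here <= ncol(px)
      sub[, keep] <- px[, here[keep], drop = FALSE]
      subs[[q]] <- sub
    }
    return(subs)
  }
  ink <- colSums(px == 255L) > 0L
  runs <- rle(ink)
  segs <- sum(runs$values)
  if (segs == 4L) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    on <- which(runs$values)
    return(lapply(on, function(k) px[, starts[k]:ends[k], drop = FALSE]))
  }
  if (segs == 1L && ncol(px) %% 4L == 0L) {
    nc <- ncol(px) %/% 4L
    return(lapply(0:3, function(q) px[, q * nc + seq_len(nc), drop = FALSE]))
  }
  stopf("expected 4 detectable sub-images, found %d ink segment(s)", segs)
}

#' Scan pixel columns for foreground positions
#'
#' For each column of a binary sub-mask, the ascending list of row indices
#' where the mask is 255; empty columns yield empty lists.
#'
#' @param submask Binary matrix with values {0, 255}.
#' @return List with one sorted integer vector per column.
#' @export
scanColumns <- function(submask) {
  stopifnot(is.matrix(submask))
  hit <- which(submask == 255L, arr.ind = TRUE)  # column-major: sorted rows
  unname(split(hit[, 1], factor(hit[, 2], levels = seq_len(ncol(submask)))))
}

#' Group column positions into the four traces
#'
#' Foreground rows in each column are clustered into runs (a row gap larger
#' than `runGapPx` starts a new run); each run's centroid is assigned to the
#' nearest trace, ties going to the upper trace, and extra runs landing on
#' the same trace are merged by pixel-weighted centroid. With
#' `tracking = TRUE` (default) "nearest" is measured against the trace's
#' previously assigned row, falling back to its static baseline, which
#' follows excursions that cross another trace's band. A trace with no run
#' in a column gets `NA`.
#'
#' @param scan Output of [scanColumns()].
#' @param baselines Strictly increasing expected rows of the four traces.
#' @param runGapPx Row gap that separates two pen strokes (default 3).
#' @param tracking Use the previous column's assignment as the reference.
#' @return Numeric matrix, columns x traces, of assigned rows (NA missing).
#' @export
groupTraces <- function(scan, baselines, runGapPx = 3L, tracking = TRUE) {
  if (is.unsorted(baselines, strictly = TRUE))
    stopf("baselines must be strictly increasing")
  rows <- unlist(scan, use.names = FALSE)
  cols <- rep(seq_along(scan), lengths(scan))
  .groupRuns(rows, cols, length(scan), baselines, runGapPx, tracking)
}

## Single pass over all (column, row) hits: break them into runs, then walk
## the runs column by column assigning each to the nearest trace.
.groupRuns <- function(rows, cols, nCols, baselines, runGapPx, tracking) {
  nT <- length(baselines)
  out <- matrix(NA_real_, nCols, nT)
  nHit <- length(rows)
  if (nHit == 0L) return(out)
  newRun <- c(TRUE, diff(cols) != 0L | diff(rows) > runGapPx)
  rid <- cumsum(newRun)
  size <- tabulate(rid)
  cen <- as.vector(rowsum(as.numeric(rows), rid)) / size
  rcol <- cols[newRun]
  track <- baselines
  k <- 1L
  nRun <- length(cen)
  while (k <= nRun) {
    j <- rcol[k]
    val <- rep(NA_real_, nT)
    wt <- rep(0L, nT)
    while (k <= nRun && rcol[k] == j) {
      d <- abs(cen[k] - track)
      tr <- which.min(d)  # which.min takes the first (upper) trace on ties
      if (wt[tr] == 0L) {
        val[tr] <- cen[k]
      } else {  # merge extra runs into the pixel-weighted centroid
        val[tr] <- (val[tr] * wt[tr] + cen[k] * size[k]) / (wt[tr] + size[k])
      }
      wt[tr] <- wt[tr] + size[k]
      k <- k + 1L
    }
    out[j, ] <- val
    if (tracking) {
      got <- !is.na(val)
      track[got] <- val[got]
    }
  }
  out
}

#' Assemble grouped traces into the 12 lead series
#'
#' Converts each trace's assigned rows to amplitudes in pixel units
#' (`baseline - row`, so upward deflections are positive), fills interior
#' gaps by linear interpolation and edge gaps by holding the nearest known
#' value, and attaches lead names from the layout. The rhythm strip (long
#' lead II, bottom trace of every sub-image) is extracted but kept out of
#' the 12-lead matrix; it is returned in the `"rhythm"` attribute as one
#' concatenated series.
#'
#' @param grouped List (one per sub-image) of [groupTraces()] matrices.
#' @param layout A [LeadLayout-class].
#' @param baselines Optional trace baselines in the same (cropped)
#'   coordinates as `grouped`; defaults to the layout's baselines.
#' @return Numeric matrix `columnsPerSubimage` x 12 (named leads), with
#'   attribute `rhythm`.
#' @export
assembleLeads <- function(grouped, layout, baselines = NULL) {
  stopifnot(length(grouped) == layout@nSubimages)
  if (is.null(baselines)) baselines <- layout@traceBaselineRows
  nc <- layout@columnsPerSubimage
  out <- matrix(NA_real_, nc, 12L, dimnames = list(NULL, LEAD_NAMES))
  rhythm <- numeric(0)
  fill <- function(v, what) {
    ok <- !is.na(v)
    if (mean(ok) < 0.5)
      stopf("trace lost: %s missing in %.0f%% of columns", what,
            100 * mean(!ok))
    if (all(ok)) return(v)
    approx(which(ok), v[ok], xout = seq_along(v), rule = 2)$y
  }
  for (q in seq_len(layout@nSubimages)) {
    g <- grouped[[q]]
    stopifnot(nrow(g) == nc, ncol(g) == layout@tracesPerSubimage)
    for (tr in seq_len(layout@tracesPerSubimage)) {
      amp <- baselines[tr] - g[, tr]   # up = positive
      if (tr <= 3L) {
        lead <- layout@leadGrid[tr, q]
        out[, lead] <- fill(amp, sprintf("lead %s (sub-image %d)", lead, q))
      } else {
        rhythm <- c(rhythm, fill(amp, sprintf("rhythm strip (sub-image %d)",
                                              q)))
      }
    }
  }
  attr(out, "rhythm") <- rhythm
  out
}
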