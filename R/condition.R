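## Signal conditioning: up-sampling, IIR low-pass filtering, per-lead
## normalization, and the full image -> tensor digitization chain.

#' Up-sample a raw lead series
#'
#' Linear interpolation from the extracted points onto
#' `round(targetRateHz * durationS)` evenly spaced points spanning the same
#' time interval; the endpoints are preserved exactly. This operation never
#' downsamples.
#'
#' @param raw Numeric vector (one lead, typically 250 points).
#' @param targetRateHz Target sampling rate (default 500).
#' @param durationS Covered duration in seconds (default 2.5).
#' @return Numeric vector of length `round(targetRateHz * durationS)`.
#' @export
upsampleSeries <- function(raw, targetRateHz = 500, durationS = 2.5) {
  stopifnot(length(raw) >= 2L)
  n <- round(targetRateHz * durationS)
  if (n < length(raw))
    stopf("target length %d is shorter than the source (%d); this operation never downsamples",
          n, length(raw))
  approx(seq(0, durationS, length.out = length(raw)), raw,
         xout = seq(0, durationS, length.out = n))$y
}

butterCoefs <- function(config, rateHz) {
  nyq <- rateHz / 2
  if (config@cutoffHz >= nyq)
    stopf("cutoff %g Hz is at or above the Nyquist frequency %g Hz",
          config@cutoffHz, nyq)
  signal::butter(config@order, config@cutoffHz / nyq, type = "low")
}

#' IIR low-pass filter
#'
#' Recursive Butterworth low-pass (default: cut-off 15 Hz, order 3). With
#' `zeroPhase` the filter runs forward and backward (zero net phase shift,
#' squared magnitude response). In both modes the signal is reflect-padded
#' by one signal length so start-up transients die out outside the window
#' (equivalently, the filter starts from its steady state; DC gain is
#' exactly 1 in the reported window).
#'
#' @param x Numeric vector, or samples x leads matrix (filtered per column).
#' @param config A [FilterConfig-class].
#' @param rateHz Sampling rate of `x` in Hz.
#' @return Filtered signal, same shape as `x`.
#' @export
lowpassFilter <- function(x, config = filterConfig(), rateHz = 500) {
  validObject(config)
  if (is.matrix(x)) {
    out <- apply(x, 2, lowpassFilter, config = config, rateHz = rateHz)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  bf <- butterCoefs(config, rateHz)
  n <- length(x)
  np <- n - 1L  # mirror reflection (~one signal length each side)
  xp <- c(rev(x[2:(np + 1L)]), x, rev(x[(n - np):(n - 1L)]))
  y <- as.numeric(signal::filter(bf, xp))
  if (config@zeroPhase)
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[np + seq_len(n)]
}

#' Normalize each lead to a unified scale
#'
#' Per-lead min-max scaling to [0, 1]; a constant lead maps to all 0.5.
#' Idempotent, and invariant under per-lead positive affine transforms.
#'
#' @param x Numeric vector or samples x leads matrix.
#' @return Normalized signal of the same shape.
#' @export
normalizeLeads <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, normalizeLeads)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  stopifnot(all(is.finite(x)))
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("%s: %s", name, conditionMessage(e)))
}

#' Digitize a 12-lead printout image
#'
#' The full chain: grid removal, crop, binarize/invert, sub-image split,
#' pixel-column scan, nearest-trace grouping, lead assembly, linear
#' up-sampling, IIR low-pass filtering and per-lead min-max normalization.
#' Deterministic; stage failures are reported with the stage name.
#'
#' @param image An [EcgImage-class] (or H x W x 3 array with `layout`
#'   supplied).
#' @param layout The printout's [LeadLayout-class].
#' @param filterCfg A [FilterConfig-class] (default 15 Hz, order 3,
#'   zero-phase Butterworth).
#' @param redThreshold,inkThreshold,marginPx,runGapPx Stage knobs; see the
#'   stage functions.
#' @param targetRateHz Output sampling rate (default 500 Hz).
#' @return A [SignalTensor-class] (1250 x 12 at the defaults) with the
#'   extracted rhythm strip in the `"rhythm"` attribute of its values.
#' @export
digitizeEcg <- function(image, layout = NULL, filterCfg = filterConfig(),
                        redThreshold = 30, inkThreshold = 128,
                        marginPx = 2L, runGapPx = 3L, targetRateHz = 500) {
  if (is(image, "EcgImage") && is.null(layout)) layout <- image@layout
  if (is.null(layout)) stopf("a LeadLayout is required")
  g <- stage("remove_grid", removeGrid(image, redThreshold))
  g <- stage("crop_to_signal", cropToSignal(g, marginPx))
  mask <- stage("binarize_invert", binarizeInvert(g, inkThreshold))
  subs <- stage("split_subimages", splitSubimages(mask, layout))
  base <- layout@traceBaselineRows - (cropOffset(mask)[1] - 1L)
  grouped <- stage("group_traces", lapply(subs, function(s) {
    hit <- which(s == 255L)
    .groupRuns((hit - 1L) %% nrow(s) + 1L, (hit - 1L) %/% nrow(s) + 1L,
               ncol(s), base, runGapPx, tracking = TRUE)
  }))
  raw <- stage("assemble_leads", assembleLeads(grouped, layout,
                                               baselines = base))
  dur <- layout@segmentDurationS
  vals <- stage("upsample", apply(raw, 2, upsampleSeries,
                                  targetRateHz = targetRateHz,
                                  durationS = dur))
  vals <- stage("lowpass_filter", lowpassFilter(vals, filterCfg,
                                                rateHz = targetRateHz))
  vals <- stage("normalize", normalizeLeads(vals))
  colnames(vals) <- LEAD_NAMES
  attr(vals, "rhythm") <- attr(raw, "rhythm")
  new("SignalTensor", values = vals, rateHz = targetRateHz, durationS = dur)
}
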