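## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## AUC by brute-force concordant-pair counting (ties count 1/2).
oracleAUC <- function(scores, pos) {
  ps <- scores[pos]
  ns <- scores[!pos]
  tot <- 0
  for (a in ps) tot <- tot + sum(a > ns) + 0.5 * sum(a == ns)
  tot / (length(ps) * length(ns))
}

## Brute-force Youden scan over every distinct threshold (rule: score >=
## threshold is positive); ties broken toward higher specificity.
oracleYouden <- function(scores, pos) {
  best <- NULL
  for (thr in sort(unique(scores), decreasing = TRUE)) {
    call <- scores >= thr
    sens <- sum(call & pos) / sum(pos)
    spec <- sum(!call & !pos) / sum(!pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(thr = thr, j = j, sens = sens, spec = spec)
  }
  best
}

## Analytic Butterworth magnitude response |H(f)| for a low-pass of the
## given order and cut-off (analog prototype).
butterMagnitude <- function(f, cutoff, order) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}

## Closed-form magnitude of the bilinear-transform digital Butterworth:
## the analog formula evaluated at prewarped frequencies.
butterMagnitudeDigital <- function(f, cutoff, order, fs) {
  ratio <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  1 / sqrt(1 + ratio^(2 * order))
}

## Amplitude of a sinusoid of known frequency in a sampled signal
## (discrete Fourier projection over an integer number of cycles).
sineAmplitude <- function(x, f, rateHz) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rateHz
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}

## Closed-form conv/pool output length under valid padding.
oracleConvLen <- function(L, k, stride) (L - k) %/% stride + 1L
oracleBlockLen <- function(L, k) {
  conv <- oracleConvLen(L, k, 3L)
  if (conv >= 5L) oracleConvLen(conv, 5L, 3L) else conv
}

## Brute-force per-column rasterization of one trace: the vertical span of
## column c runs between the rounded midpoints toward its neighbours.
oracleTraceSpans <- function(rows, H) {
  nc <- length(rows)
  lo <- hi <- integer(nc)
  for (c in seq_len(nc)) {
    lft <- if (c == 1L) rows[1] else round((rows[c - 1] + rows[c]) / 2)
    rgt <- if (c == nc) rows[nc] else round((rows[c] + rows[c + 1]) / 2)
    lo[c] <- max(1L, min(rows[c], lft, rgt))
    hi[c] <- min(H, max(rows[c], lft, rgt))
  }
  list(lo = lo, hi = hi)
}

## Small noise-free layout/cohort helpers shared by tests.
noiseFreeRanges <- function() {
  r <- vpcECG:::defaultParamsRanges()
  r$baselineWanderAmp <- c(0, 0)
  r$noiseSd <- c(0, 0)
  r
}

## A quick single record (noise free unless stated).
quickRecord <- function(seed = 1, label = "NOR", effect = 0, noiseSd = 0) {
  p <- waveformParams(classLabel = label, classEffectSize = effect,
                      noiseSd = noiseSd)
  s <- generateWaveform(p, seed = seed)
  renderEcgImage(s, recordId = sprintf("R%03d", seed), patientId = "P001",
                 label = label)
}
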