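## Synthetic 12-lead ECG generation: ground-truth waveforms, red-grid
## printout rendering with exact per-pixel truth, and labeled two-class
## cohorts with patient-level record grouping.

## Deterministic per-lead projection of the common waveform template.
## Signs and magnitudes loosely follow typical limb/chest lead polarity
## (aVR and the right precordials predominantly negative).
LEAD_SCALE <- c(I = 0.60, II = 1.00, III = 0.50, aVR = -0.90, aVL = 0.35,
                aVF = 0.70, V1 = -0.70, V2 = -0.40, V3 = 0.45, V4 = 1.10,
                V5 = 1.00, V6 = 0.80)

gaussBump <- function(t, center, fwhm, amp) {
  sd <- fwhm / 2.355
  amp * exp(-0.5 * ((t - center) / sd)^2)
}

#' Generate ground-truth 12-lead waveforms
#'
#' Builds a repeating P-QRS-T template at the requested heart rate and
#' projects it onto the 12 leads through a fixed per-lead scaling table.
#' VPC-class records additionally receive a smooth morphology perturbation
#' scaled by `classEffectSize`: a low-frequency hump on the terminal portion
#' of the QRS complex plus a proportional T-wave amplitude increase. At
#' effect size 0 the two class generators are identical.
#'
#' @param params A [WaveformParams-class].
#' @param durationS Signal duration in seconds (default 2.5).
#' @param rateHz Sampling rate in Hz (default 500).
#' @param seed Integer seed for the beat phase, baseline wander phases and
#'   noise realization; identical seeds give identical output.
#' @return A [LeadSignalSet-class] with `round(durationS * rateHz)` samples
#'   per lead.
#' @examples
#' s <- generateWaveform(waveformParams(), seed = 1)
#' dim(leadSignals(s))  # 1250 x 12
#' @export
generateWaveform <- function(params, durationS = 2.5, rateHz = 500,
                             seed = NULL) {
  stopifnot(is(params, "WaveformParams"))
  validObject(params)
  if (durationS <= 0) stopf("durationS must be positive, got %g", durationS)
  if (rateHz <= 0) stopf("rateHz must be positive, got %g", rateHz)
  n <- round(durationS * rateHz)
  t <- (seq_len(n) - 1) / rateHz
  rr <- 60 / params@heartRateBpm
  eff <- if (params@classLabel == "VPC") params@classEffectSize else 0

  withSeed(seed, {
    phase <- runif(1, 0, rr)
    ## beat centers covering the window plus margins
    centers <- seq(-rr, durationS + rr, by = rr) + phase
    base <- numeric(n)
    tAmpEff <- params@tAmp * (1 + 0.4 * eff)
    for (cR in centers) {
      base <- base +
        gaussBump(t, cR - 0.17, params@pWidthS, params@pAmp) +
        gaussBump(t, cR - 0.035, 0.030, -0.12 * params@qrsAmp) +
        gaussBump(t, cR, params@qrsWidthS, params@qrsAmp) +
        gaussBump(t, cR + 0.035, 0.035, -0.20 * params@qrsAmp) +
        gaussBump(t, cR + 0.30, params@tWidthS, tAmpEff)
      if (eff > 0)  # widened low-frequency component adjacent to the QRS
        base <- base + gaussBump(t, cR + 0.16, 0.14,
                                 0.4 * eff * params@qrsAmp)
    }
    sig <- outer(base, LEAD_SCALE)
    if (params@baselineWanderAmp > 0) {
      ph <- runif(12, 0, 2 * pi)
      wander <- params@baselineWanderAmp *
        sin(outer(2 * pi * 0.33 * t, rep(1, 12)) +
            matrix(ph, n, 12, byrow = TRUE))
      sig <- sig + wander
    }
    if (params@noiseSd > 0)
      sig <- sig + matrix(rnorm(n * 12, sd = params@noiseSd), n, 12)
    colnames(sig) <- LEAD_NAMES
    new("LeadSignalSet", signals = sig, rateHz = rateHz)
  })
}

## Resample one lead to exactly nCols points spanning the same interval.
resampleToColumns <- function(x, nCols) {
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = nCols))$y
}

## Column-wise vertical spans for one trace: each column's ink spans from/to
## the rounded midpoints toward the neighbouring samples, so adjacent
## columns share a row (4-connected pen stroke) and the span's center stays
## at the sample's own row.
traceSpans <- function(rows, lineWidthPx, H) {
  nc <- length(rows)
  mid <- round((rows[-nc] + rows[-1]) / 2)
  lo <- pmin(rows, c(rows[1], mid), c(mid, rows[nc]))
  hi <- pmax(rows, c(rows[1], mid), c(mid, rows[nc]))
  if (lineWidthPx > 1L) {
    lo <- lo - (lineWidthPx - 1L) %/% 2L
    hi <- hi + lineWidthPx %/% 2L
  }
  list(lo = clampInt(lo, 1L, H), hi = clampInt(hi, 1L, H))
}

#' Render a 12-lead printout image with ground truth
#'
#' Draws the 12 leads (plus the long lead II rhythm strip) as dark traces
#' over a periodic red grid, in the standard layout of four vertical
#' sub-images with four traces per pixel column. Amplitude `a` at baseline
#' row `b` is drawn at row `b - round(pxPerUnit * a)` (image rows grow
#' downward). The returned record carries the exact per-pixel
#' {background, grid, trace} classification and, per (sub-image, trace,
#' column) cell, the drawn sample row.
#'
#' @param signals A [LeadSignalSet-class]; each lead is resampled to
#'   `columnsPerSubimage` points for drawing.
#' @param layout A [LeadLayout-class].
#' @param gridColor,majorGridColor RGB triples (0..255) of the minor/major
#'   grid lines; minor spacing 5 px, major 25 px.
#' @param traceColor RGB triple of the trace ink; must differ from the grid.
#' @param lineWidthPx Trace thickness in pixels.
#' @param inkJitter Standard deviation of optional per-pixel ink intensity
#'   jitter (0 disables it).
#' @param seed Seed for the ink jitter.
#' @param recordId,patientId,label Metadata stored on the record.
#' @return A [SyntheticRecord-class]. Trace excursions beyond the image are
#'   clipped and flagged in the `clipped` slot.
#' @export
renderEcgImage <- function(signals, layout = standardLeadLayout(),
                           gridColor = c(240L, 170L, 170L),
                           majorGridColor = c(230L, 120L, 120L),
                           traceColor = c(30L, 30L, 30L),
                           lineWidthPx = 1L, inkJitter = 0, seed = NULL,
                           recordId = "synthetic", patientId = "synthetic",
                           label = "NOR") {
  stopifnot(is(signals, "LeadSignalSet"), is(layout, "LeadLayout"))
  if (identical(as.integer(gridColor), as.integer(traceColor)))
    stopf("gridColor and traceColor must differ")
  H <- layout@imageHeight
  nc <- layout@columnsPerSubimage
  W <- layout@nSubimages * nc
  npix <- as.numeric(H) * W

  px <- array(255L, dim = c(H, W, 3L))
  mask <- matrix(0L, H, W)

  ## periodic grid: minor every 5 px, major every 25 px
  minorR <- seq(1L, H, by = 5L); minorC <- seq(1L, W, by = 5L)
  majorR <- seq(1L, H, by = 25L); majorC <- seq(1L, W, by = 25L)
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[minorR, ] <- gridColor[ch]
    plane[, minorC] <- gridColor[ch]
    plane[majorR, ] <- majorGridColor[ch]
    plane[, majorC] <- majorGridColor[ch]
    px[, , ch] <- plane
  }
  mask[minorR, ] <- 1L; mask[, minorC] <- 1L
  mask[majorR, ] <- 1L; mask[, majorC] <- 1L

  sig <- leadSignals(signals)
  clipped <- FALSE
  rowsPerSub <- vector("list", layout@nSubimages)
  linAll <- integer(0)

  for (q in seq_len(layout@nSubimages)) {
    rowsMat <- matrix(0L, nc, layout@tracesPerSubimage)
    for (tr in seq_len(layout@tracesPerSubimage)) {
      lead <- if (tr <= 3L) layout@leadGrid[tr, q] else "II"  # rhythm strip
      amp <- resampleToColumns(sig[, lead], nc)
      rows <- round(layout@traceBaselineRows[tr] - layout@pxPerUnit * amp)
      if (any(rows < 1 | rows > H)) clipped <- TRUE
      rows <- clampInt(rows, 1L, H)
      rowsMat[, tr] <- as.integer(rows)
      sp <- traceSpans(rows, as.integer(lineWidthPx), H)
      h <- sp$hi - sp$lo + 1L
      absCol <- (q - 1L) * nc + seq_len(nc)
      rowIdx <- sequence(h) - 1L + rep(sp$lo, h)
      colIdx <- rep(absCol, h)
      linAll <- c(linAll, rowIdx + (colIdx - 1L) * H)
    }
    rowsPerSub[[q]] <- rowsMat
  }

  linAll <- unique(linAll)
  mask[linAll] <- 2L
  ink <- matrix(rep(as.integer(traceColor), each = length(linAll)),
                ncol = 3L)
  if (inkJitter > 0) {
    ink <- withSeed(seed, ink + matrix(as.integer(round(
      rnorm(length(ink), 0, inkJitter))), ncol = 3L))
    ink <- clampInt(ink, 0L, 100L)  # keep the ink unambiguously dark
  }
  for (ch in 1:3) px[linAll + (ch - 1) * npix] <- ink[, ch]

  img <- new("EcgImage", pixels = px, layout = layout, sourceId = recordId)
  new("SyntheticRecord", recordId = recordId, patientId = patientId,
      label = label, image = img, truth = signals, truthMask = mask,
      truthRows = rowsPerSub, clipped = clipped)
}

defaultParamsRanges <- function() {
  list(heartRateBpm = c(55, 95), pAmp = c(0.10, 0.20),
       qrsAmp = c(0.80, 1.20), tAmp = c(0.20, 0.40),
       pWidthS = c(0.08, 0.10), qrsWidthS = c(0.07, 0.09),
       tWidthS = c(0.14, 0.18), baselineWanderAmp = c(0, 0.05),
       noiseSd = c(0.005, 0.02))
}

#' Generate a labeled synthetic cohort
#'
#' Draws `nPatients` patients, assigns `round(classBalance * nPatients)` of
#' them (shuffled) to the VPC class, draws each patient's waveform
#' parameters once from `paramsRanges`, and renders an independent record
#' for each of the patient's 1..k ECGs (per-record beat phase, wander and
#' noise realizations through per-record seeds). All records of a patient
#' share the patient's label.
#'
#' @param nPatients Number of patients (>= 2).
#' @param recordsPerPatient Length-2 integer range; each patient's record
#'   count is drawn uniformly from it. Default `c(1, 4)`.
#' @param classBalance Proportion of VPC patients in (0, 1).
#' @param classEffectSize Morphology effect size applied to VPC patients.
#' @param paramsRanges Named list of length-2 ranges for the per-patient
#'   waveform parameters; see `vpcECG:::defaultParamsRanges()`.
#' @param seed Master seed; the whole cohort (manifest included) is a
#'   deterministic function of it.
#' @param layout,rateHz,durationS Rendering geometry and signal format.
#' @param materialize If TRUE (default) render all records now; if FALSE
#'   only the manifest and parameters are kept and [cohortRecord()]
#'   regenerates records on demand (constant memory for large cohorts).
#' @return An [EcgCohort-class].
#' @export
generateCohort <- function(nPatients, recordsPerPatient = c(1L, 4L),
                           classBalance = 0.5, classEffectSize = 1,
                           paramsRanges = defaultParamsRanges(), seed = 1,
                           layout = standardLeadLayout(), rateHz = 500,
                           durationS = 2.5, materialize = TRUE) {
  if (nPatients < 2) stopf("need at least 2 patients, got %d", nPatients)
  if (classBalance <= 0 || classBalance >= 1)
    stopf("classBalance must be in (0, 1)")
  nVpc <- round(classBalance * nPatients)
  if (nVpc < 1L || nVpc > nPatients - 1L)
    stopf("classBalance %g leaves a class empty with %d patients",
          classBalance, nPatients)
  rp <- as.integer(recordsPerPatient)
  stopifnot(length(rp) == 2L, rp[1] >= 1L, rp[2] >= rp[1])

  withSeed(seed, {
    pid <- sprintf("P%04d", seq_len(nPatients))
    labels <- sample(c(rep("VPC", nVpc), rep("NOR", nPatients - nVpc)))
    nrec <- if (rp[1] == rp[2]) rep(rp[1], nPatients)
            else sample(seq(rp[1], rp[2]), nPatients, replace = TRUE)
    pparams <- lapply(seq_len(nPatients), function(i) {
      draw <- function(nm) runif(1, paramsRanges[[nm]][1],
                                 paramsRanges[[nm]][2])
      waveformParams(
        heartRateBpm = draw("heartRateBpm"), pAmp = draw("pAmp"),
        qrsAmp = draw("qrsAmp"), tAmp = draw("tAmp"),
        pWidthS = draw("pWidthS"), qrsWidthS = draw("qrsWidthS"),
        tWidthS = draw("tWidthS"),
        baselineWanderAmp = draw("baselineWanderAmp"),
        noiseSd = draw("noiseSd"), classLabel = labels[i],
        classEffectSize = if (labels[i] == "VPC") classEffectSize else 0)
    })
    names(pparams) <- pid
    total <- sum(nrec)
    manifest <- data.frame(
      record_id = sprintf("R%05d", seq_len(total)),
      patient_id = rep(pid, nrec),
      label = rep(labels, nrec),
      record_seed = sample.int(.Machine$integer.max - 1L, total),
      stringsAsFactors = FALSE)

    cohort <- new("EcgCohort", manifest = manifest, records = list(),
                  patientParams = pparams, layout = layout, rateHz = rateHz,
                  durationS = durationS)
    if (materialize)
      cohort@records <- lapply(seq_len(total),
                               function(i) cohortRecord(cohort, i))
    cohort
  })
}

#' Materialize one cohort record
#'
#' Returns record `i` of a cohort, rendering it deterministically from the
#' manifest's per-record seed if the cohort was generated with
#' `materialize = FALSE`.
#'
#' @param cohort An [EcgCohort-class].
#' @param i Record index (row of the manifest).
#' @return A [SyntheticRecord-class].
#' @export
cohortRecord <- function(cohort, i) {
  stopifnot(is(cohort, "EcgCohort"))
  if (length(cohort@records) >= i && !is.null(cohort@records[i][[1]]))
    return(cohort@records[[i]])
  m <- cohort@manifest[i, ]
  params <- cohort@patientParams[[m$patient_id]]
  sig <- generateWaveform(params, durationS = cohort@durationS,
                          rateHz = cohort@rateHz, seed = m$record_seed)
  renderEcgImage(sig, layout = cohort@layout, recordId = m$record_id,
                 patientId = m$patient_id, label = m$label)
}

#' Write a cohort to disk
#'
#' Writes each record's printout as PNG, its ground-truth signals as CSV
#' and its truth mask as a grayscale PNG (0 background, 127 grid,
#' 255 trace), plus a manifest CSV with columns record_id, patient_id,
#' label, image_path, truth_path.
#'
#' @param cohort An [EcgCohort-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame that was written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohortManifest(cohort)
  m$image_path <- file.path(dir, paste0(m$record_id, ".png"))
  m$truth_path <- file.path(dir, paste0(m$record_id, "_truth.csv"))
  for (i in seq_len(nrow(m))) {
    rec <- cohortRecord(cohort, i)
    png::writePNG(aperm(imagePixels(rec), c(1, 2, 3)) / 255, m$image_path[i])
    write.csv(leadSignals(truthSignals(rec)), m$truth_path[i],
              row.names = FALSE)
    png::writePNG(truthMask(rec) * 127.5 / 255, file.path(
      dir, paste0(m$record_id[i], "_mask.png")))
  }
  write.csv(m[, c("record_id", "patient_id", "label", "image_path",
                  "truth_path")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
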