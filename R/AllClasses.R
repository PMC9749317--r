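## S4 containers for the digitization pipeline. Validity methods encode the
## structural invariants the downstream stages rely on.

#' Waveform generator parameters
#'
#' Parameters of the synthetic P-QRS-T waveform generator. Amplitudes are in
#' arbitrary units (the pipeline normalizes amplitude away); widths are the
#' full width at half maximum of the corresponding deflection, in seconds.
#'
#' @slot heartRateBpm Heart rate in beats per minute.
#' @slot pAmp,qrsAmp,tAmp Amplitudes of the P wave, QRS complex and T wave.
#' @slot pWidthS,qrsWidthS,tWidthS Deflection widths (seconds).
#' @slot baselineWanderAmp Amplitude of a slow sinusoidal baseline drift.
#' @slot noiseSd Standard deviation of additive white noise.
#' @slot classLabel `"VPC"` or `"NOR"`.
#' @slot classEffectSize Magnitude of the smooth morphology perturbation
#'   applied to VPC-class records; 0 makes the two classes identically
#'   distributed.
#' @export
setClass("WaveformParams", representation(
  heartRateBpm = "numeric", pAmp = "numeric", qrsAmp = "numeric",
  tAmp = "numeric", pWidthS = "numeric", qrsWidthS = "numeric",
  tWidthS = "numeric", baselineWanderAmp = "numeric", noiseSd = "numeric",
  classLabel = "character", classEffectSize = "numeric"),
  prototype(heartRateBpm = 75, pAmp = 0.15, qrsAmp = 1, tAmp = 0.3,
            pWidthS = 0.09, qrsWidthS = 0.08, tWidthS = 0.16,
            baselineWanderAmp = 0, noiseSd = 0, classLabel = "NOR",
            classEffectSize = 0))

setValidity("WaveformParams", function(object) {
  msg <- character()
  if (object@heartRateBpm <= 0) msg <- c(msg, "heartRateBpm must be positive")
  if (object@qrsWidthS <= 0 || object@pWidthS <= 0 || object@tWidthS <= 0)
    msg <- c(msg, "deflection widths must be positive")
  if (object@qrsWidthS >= 60 / object@heartRateBpm)
    msg <- c(msg, "qrsWidthS must be shorter than the beat period")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@baselineWanderAmp < 0)
    msg <- c(msg, "baselineWanderAmp must be non-negative")
  if (!object@classLabel %in% c("VPC", "NOR"))
    msg <- c(msg, "classLabel must be 'VPC' or 'NOR'")
  if (object@classEffectSize < 0)
    msg <- c(msg, "classEffectSize must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn WaveformParams-class Constructor.
#' @param ... Slot values overriding the defaults.
#' @export
waveformParams <- function(...) new("WaveformParams", ...)

#' Printout layout geometry
#'
#' Geometry of a 12-lead ECG printout: four vertical sub-images of
#' `columnsPerSubimage` pixel columns, each carrying three leads plus the
#' long lead II rhythm strip (four traces per column). `leadGrid` maps the
#' three lead rows of each sub-image to lead names in the standard
#' arrangement; the fourth trace row is always the rhythm strip.
#'
#' @slot nSubimages,columnsPerSubimage,tracesPerSubimage Integer geometry.
#' @slot leadGrid 3 x 4 character matrix: lead name at (trace row, sub-image).
#' @slot traceBaselineRows Strictly increasing vertical pixel positions of
#'   the four trace baselines.
#' @slot pxPerUnit Vertical pixels per amplitude unit.
#' @slot segmentDurationS Seconds of signal per sub-image column block.
#' @slot imageHeight Rendered image height in pixels.
#' @export
setClass("LeadLayout", representation(
  nSubimages = "integer", columnsPerSubimage = "integer",
  tracesPerSubimage = "integer", leadGrid = "matrix",
  traceBaselineRows = "numeric", pxPerUnit = "numeric",
  segmentDurationS = "numeric", imageHeight = "integer"))

setValidity("LeadLayout", function(object) {
  msg <- character()
  if (object@nSubimages != length(object@traceBaselineRows) ||
      object@tracesPerSubimage != length(object@traceBaselineRows))
    msg <- c(msg, "traceBaselineRows must have one entry per trace row")
  if (is.unsorted(object@traceBaselineRows, strictly = TRUE))
    msg <- c(msg, "traceBaselineRows must be strictly increasing")
  if (!identical(dim(object@leadGrid), c(3L, object@nSubimages)))
    msg <- c(msg, "leadGrid must be 3 x nSubimages")
  if (!setequal(as.vector(object@leadGrid), LEAD_NAMES))
    msg <- c(msg, "leadGrid must map exactly the 12 standard leads")
  if (object@pxPerUnit <= 0) msg <- c(msg, "pxPerUnit must be positive")
  if (object@segmentDurationS <= 0)
    msg <- c(msg, "segmentDurationS must be positive")
  if (max(object@traceBaselineRows) >= object@imageHeight)
    msg <- c(msg, "baselines must fit within imageHeight")
  if (length(msg)) msg else TRUE
})

#' @describeIn LeadLayout-class Default layout: 4 sub-images x 250 columns,
#'   leads arranged (I,II,III | aVR,aVL,aVF | V1,V2,V3 | V4,V5,V6) with the
#'   rhythm strip as the bottom trace; baselines at rows 35/95/155/215 in a
#'   250-pixel-high image, 20 px per amplitude unit, 2.5 s per sub-image.
#' @param pxPerUnit,traceBaselineRows,imageHeight Optional geometry
#'   overrides.
#' @export
standardLeadLayout <- function(pxPerUnit = 20,
                               traceBaselineRows = c(35, 95, 155, 215),
                               imageHeight = 250L) {
  new("LeadLayout",
      nSubimages = 4L, columnsPerSubimage = 250L, tracesPerSubimage = 4L,
      leadGrid = matrix(LEAD_NAMES, nrow = 3L, ncol = 4L),
      traceBaselineRows = as.numeric(traceBaselineRows),
      pxPerUnit = pxPerUnit, segmentDurationS = 2.5,
      imageHeight = as.integer(imageHeight))
}

#' Multi-lead signal container
#'
#' A set of 12 named per-lead sample sequences with a common sampling rate.
#'
#' @slot signals Numeric matrix, samples x 12, column names the lead names.
#' @slot rateHz Sampling rate in Hz.
#' @export
setClass("LeadSignalSet",
         representation(signals = "matrix", rateHz = "numeric"))

setValidity("LeadSignalSet", function(object) {
  msg <- character()
  if (ncol(object@signals) != 12L ||
      !identical(colnames(object@signals), LEAD_NAMES))
    msg <- c(msg, "signals must have the 12 standard leads as columns")
  if (object@rateHz <= 0) msg <- c(msg, "rateHz must be positive")
  if (length(msg)) msg else TRUE
})

#' 12-lead printout image
#'
#' An RGB raster of a 12-lead ECG printout plus its layout metadata.
#'
#' @slot pixels H x W x 3 integer array with values in 0..255.
#' @slot layout A [LeadLayout-class] describing the printed geometry.
#' @slot sourceId Identifier of the source record.
#' @export
setClass("EcgImage", representation(
  pixels = "array", layout = "LeadLayout", sourceId = "character"))

setValidity("EcgImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) return("pixels must be H x W x 3")
  if (d[1] < 1L || d[2] < 1L) return("image must be non-empty")
  r <- range(object@pixels)
  if (r[1] < 0 || r[2] > 255) return("pixel values must lie in [0, 255]")
  TRUE
})

#' Binary ink mask
#'
#' Trace ink mask after grid removal, inversion and thresholding:
#' foreground (ink) is exactly 255, background exactly 0.
#'
#' @slot pixels H x W integer matrix with values in {0, 255}.
#' @slot cropOffset Length-2 integer (row, col) position of this mask's
#'   top-left corner within the original image (1-based).
#' @export
setClass("TraceMask",
         representation(pixels = "matrix", cropOffset = "integer"))

setValidity("TraceMask", function(object) {
  if (!all(object@pixels %in% c(0L, 255L)))
    return("mask values must be exactly 0 or 255")
  if (length(object@cropOffset) != 2L) return("cropOffset must be (row, col)")
  TRUE
})

#' Conditioned signal tensor
#'
#' The 1250 x 12 conditioned array fed to the time-series models.
#'
#' @slot values 1250 x 12 numeric matrix (samples x leads).
#' @slot rateHz Sampling rate (500 Hz).
#' @slot durationS Duration in seconds (2.5 s).
#' @export
setClass("SignalTensor", representation(
  values = "matrix", rateHz = "numeric", durationS = "numeric"))

setValidity("SignalTensor", function(object) {
  msg <- character()
  want <- round(object@rateHz * object@durationS)
  if (nrow(object@values) != want)
    msg <- c(msg, sprintf("values must have %d rows (rate x duration)", want))
  if (ncol(object@values) != 12L ||
      !identical(colnames(object@values), LEAD_NAMES))
    msg <- c(msg, "values must have the 12 standard leads as columns")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Synthetic record with ground truth
#'
#' One rendered synthetic ECG record: the printout image, the ground-truth
#' waveforms it was rendered from, a per-pixel {background, grid, trace}
#' classification, and the exact drawn trace row of every (sub-image, trace,
#' column) cell.
#'
#' @slot recordId,patientId,label Identifiers; label is `"VPC"` or `"NOR"`.
#' @slot image The rendered [EcgImage-class].
#' @slot truth Ground-truth [LeadSignalSet-class].
#' @slot truthMask H x W integer matrix: 0 background, 1 grid, 2 trace.
#' @slot truthRows List (one per sub-image) of columns x traces matrices of
#'   drawn trace rows (before the connecting spans are added).
#' @slot clipped TRUE if any trace excursion had to be clipped to the image.
#' @export
setClass("SyntheticRecord", representation(
  recordId = "character", patientId = "character", label = "character",
  image = "EcgImage", truth = "LeadSignalSet", truthMask = "matrix",
  truthRows = "list", clipped = "logical"))

setValidity("SyntheticRecord", function(object) {
  msg <- character()
  if (!object@label %in% c("VPC", "NOR"))
    msg <- c(msg, "label must be 'VPC' or 'NOR'")
  if (!identical(dim(object@truthMask), dim(object@image@pixels)[1:2]))
    msg <- c(msg, "truthMask must match the image dimensions")
  if (!all(object@truthMask %in% 0:2))
    msg <- c(msg, "truthMask values must be 0 (bg), 1 (grid) or 2 (trace)")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort
#'
#' A labeled two-class cohort of synthetic records with patient-level
#' grouping. The manifest always carries one row per record (record id,
#' patient id, label, and the per-record generation seed); `records` holds
#' materialized [SyntheticRecord-class] objects, or is empty when the cohort
#' was generated with `materialize = FALSE`, in which case [cohortRecord()]
#' regenerates any record deterministically from the manifest.
#'
#' @slot manifest data.frame with columns record_id, patient_id, label,
#'   record_seed.
#' @slot records List of materialized records (possibly empty).
#' @slot patientParams Named list of per-patient [WaveformParams-class].
#' @slot layout The shared [LeadLayout-class].
#' @slot rateHz,durationS Waveform sampling rate and duration.
#' @export
setClass("EcgCohort", representation(
  manifest = "data.frame", records = "list", patientParams = "list",
  layout = "LeadLayout", rateHz = "numeric", durationS = "numeric"))

setValidity("EcgCohort", function(object) {
  m <- object@manifest
  need <- c("record_id", "patient_id", "label", "record_seed")
  if (!all(need %in% names(m)))
    return(paste("manifest must have columns", paste(need, collapse = ", ")))
  lab <- tapply(m$label, m$patient_id, function(x) length(unique(x)))
  if (any(lab > 1L)) return("a patient cannot carry two labels")
  if (anyDuplicated(m$record_id)) return("record ids must be unique")
  TRUE
})

#' IIR low-pass filter configuration
#'
#' @slot cutoffHz Cut-off frequency (default 15 Hz).
#' @slot order Filter order (default 3).
#' @slot family Filter family; `"butter"` (Butterworth) is implemented.
#' @slot zeroPhase Apply forward and backward (zero net phase shift,
#'   squared magnitude response). Default TRUE.
#' @export
setClass("FilterConfig", representation(
  cutoffHz = "numeric", order = "integer", family = "character",
  zeroPhase = "logical"),
  prototype(cutoffHz = 15, order = 3L, family = "butter", zeroPhase = TRUE))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@cutoffHz <= 0) msg <- c(msg, "cutoffHz must be positive")
  if (object@order < 1L) msg <- c(msg, "order must be >= 1")
  if (!identical(object@family, "butter"))
    msg <- c(msg, "only the Butterworth family is implemented")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterConfig-class Constructor.
#' @param cutoffHz,order,family,zeroPhase See slots.
#' @export
filterConfig <- function(cutoffHz = 15, order = 3L, family = "butter",
                         zeroPhase = TRUE) {
  new("FilterConfig", cutoffHz = cutoffHz, order = as.integer(order),
      family = family, zeroPhase = zeroPhase)
}

#' Diagnostic evaluation report
#'
#' Threshold-based diagnostic performance at the Youden-optimal cut-point,
#' plus the ROC AUC, each with a stratified-bootstrap percentile 95%
#' confidence interval.
#'
#' @slot threshold Youden-optimal score cut-point.
#' @slot auc Area under the ROC curve.
#' @slot metrics Named numeric: accuracy, sensitivity, specificity, ppv, npv.
#' @slot ci 2 x 6 matrix of lower/upper 95% bounds (auc + the five metrics).
#' @slot counts Named integer: TP, FP, TN, FN at the threshold.
#' @slot nBoot Number of bootstrap resamples used for the intervals.
#' @export
setClass("EvalReport", representation(
  threshold = "numeric", auc = "numeric", metrics = "numeric",
  ci = "matrix", counts = "integer", nBoot = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  need <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  if (!all(need %in% names(object@metrics)))
    msg <- c(msg, "metrics must include accuracy/sensitivity/specificity/ppv/npv")
  est <- c(auc = object@auc, object@metrics)
  for (nm in colnames(object@ci)) {
    if (nm %in% names(est) && is.finite(est[[nm]]) &&
        all(is.finite(object@ci[, nm])) &&
        (est[[nm]] < object@ci[1, nm] - 1e-9 ||
         est[[nm]] > object@ci[2, nm] + 1e-9))
      msg <- c(msg, sprintf("CI for %s does not contain its estimate", nm))
  }
  if (length(msg)) msg else TRUE
})

#' CNN model handle
#'
#' A built classifier: the architecture specification plus the network's
#' parameter tree. Weights live in `net`; use [trainModel()] to fit and
#' [predictProba()] for inference.
#'
#' @slot spec The architecture specification list (see [buildImageModel()],
#'   [buildTsModel()]).
#' @slot net Internal layer tree with weights.
#' @slot inputKind `"image"`, `"ts"` or `"ts_multi"`.
#' @export
setClass("CnnModel", representation(
  spec = "list", net = "list", inputKind = "character"))
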