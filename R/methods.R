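## Accessors and show methods.

#' @rdname accessors
#' @aliases leadSignals,LeadSignalSet-method
setMethod("leadSignals", "LeadSignalSet", function(x) x@signals)

#' @rdname accessors
setMethod("sampleRate", "LeadSignalSet", function(x) x@rateHz)

#' @rdname accessors
setMethod("sampleRate", "SignalTensor", function(x) x@rateHz)

#' @rdname accessors
setMethod("leadNames", "LeadSignalSet", function(x) colnames(x@signals))

#' @rdname accessors
setMethod("leadNames", "SignalTensor", function(x) colnames(x@values))

#' @rdname accessors
setMethod("tensorValues", "SignalTensor", function(x) x@values)

#' @rdname accessors
setMethod("imagePixels", "EcgImage", function(x) x@pixels)

#' @rdname accessors
setMethod("maskPixels", "TraceMask", function(x) x@pixels)

#' @rdname accessors
setMethod("cropOffset", "TraceMask", function(x) x@cropOffset)

#' @rdname accessors
setMethod("recordId", "SyntheticRecord", function(x) x@recordId)

#' @rdname accessors
setMethod("patientId", "SyntheticRecord", function(x) x@patientId)

#' @rdname accessors
setMethod("recordLabel", "SyntheticRecord", function(x) x@label)

#' @rdname accessors
setMethod("truthSignals", "SyntheticRecord", function(x) x@truth)

#' @rdname accessors
setMethod("truthMask", "SyntheticRecord", function(x) x@truthMask)

#' @rdname accessors
setMethod("truthRows", "SyntheticRecord", function(x) x@truthRows)

#' @rdname accessors
setMethod("imagePixels", "SyntheticRecord", function(x) x@image@pixels)

#' @rdname accessors
setMethod("cohortManifest", "EcgCohort", function(x) x@manifest)

#' @rdname accessors
setMethod("nRecords", "EcgCohort", function(x) nrow(x@manifest))

setMethod("show", "LeadSignalSet", function(object) {
  cat(sprintf("LeadSignalSet: %d samples x %d leads @ %g Hz\n",
              nrow(object@signals), ncol(object@signals), object@rateHz))
})

setMethod("show", "EcgImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("EcgImage '%s': %d x %d RGB, %d sub-images of %d columns\n",
              object@sourceId, d[1], d[2], object@layout@nSubimages,
              object@layout@columnsPerSubimage))
})

setMethod("show", "TraceMask", function(object) {
  cat(sprintf("TraceMask: %d x %d, %d ink pixels, crop offset (%d, %d)\n",
              nrow(object@pixels), ncol(object@pixels),
              sum(object@pixels == 255L),
              object@cropOffset[1], object@cropOffset[2]))
})

setMethod("show", "SignalTensor", function(object) {
  cat(sprintf("SignalTensor: %d x %d (%.1f s @ %g Hz), range [%.3f, %.3f]\n",
              nrow(object@values), ncol(object@values), object@durationS,
              object@rateHz, min(object@values), max(object@values)))
})

setMethod("show", "SyntheticRecord", function(object) {
  cat(sprintf("SyntheticRecord %s (patient %s, label %s)%s\n",
              object@recordId, object@patientId, object@label,
              if (object@clipped) " [clipped]" else ""))
  show(object@image)
})

setMethod("show", "EcgCohort", function(object) {
  m <- object@manifest
  cat(sprintf("EcgCohort: %d records / %d patients (%d VPC, %d NOR)%s\n",
              nrow(m), length(unique(m$patient_id)),
              sum(m$label == "VPC"), sum(m$label == "NOR"),
              if (length(object@records)) "" else " [not materialized]"))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport @ threshold %.4f (Youden), %d bootstrap reps\n",
              object@threshold, object@nBoot))
  est <- c(auc = object@auc, object@metrics)
  for (nm in names(est))
    cat(sprintf("  %-12s %.3f  (95%% CI %.3f-%.3f)\n", nm, est[[nm]],
                object@ci[1, nm], object@ci[2, nm]))
  cat(sprintf("  counts: TP %d  FP %d  TN %d  FN %d\n",
              object@counts["TP"], object@counts["FP"],
              object@counts["TN"], object@counts["FN"]))
})

setMethod("show", "CnnModel", function(object) {
  cat(sprintf("CnnModel (%s input)\n", object@inputKind))
  s <- modelSummary(object)
  cat(sprintf("  %d layers, %d trainable parameters\n",
              nrow(s), sum(s$n_params)))
  invisible(object)
})
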