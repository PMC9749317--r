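## Kernel-size sweep harness over the time-series model families.

#' Sweep model specs over a dataset
#'
#' Trains and evaluates one model per spec, each with a fresh
#' seed-derived initialization (`baseSeed + index`), and tabulates the
#' results in the kernel-size x {accuracy, ROC AUC, sensitivity,
#' specificity} shape of the study's sweep table. Per-spec failures are
#' recorded as NA rows without aborting the sweep.
#'
#' @param specs List of model specs ([tsModelSpec()] /
#'   [imageModelSpec()]), e.g. from [kernelSizeGrid()].
#' @param train,validation,test Datasets as in [trainModel()].
#' @param config A [trainConfig()]; its seed is offset per spec.
#' @param baseSeed Base seed for initialization/training.
#' @param nBoot Bootstrap reps for the per-cell evaluation.
#' @return data.frame: mode, kernel_size, accuracy, auc, sensitivity,
#'   specificity (plus error messages in attribute `"failures"`).
#' @export
sweepModels <- function(specs, train, validation, test,
                        config = trainConfig(), baseSeed = 1L,
                        nBoot = 200L) {
  stopifnot(length(specs) >= 1L)
  failures <- character(0)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    row <- data.frame(
      mode = if (identical(sp$type, "image")) sp$backboneId
             else sp$mode,
      kernel_size = if (identical(sp$type, "ts")) sp$kernelSize else NA,
      accuracy = NA_real_, auc = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_)
    tryCatch({
      cfg <- config
      cfg$seed <- config$seed + i
      model <- if (identical(sp$type, "image"))
        buildImageModel(sp, seed = baseSeed + i)
      else buildTsModel(sp, seed = baseSeed + i)
      fit <- trainModel(model, train, validation, cfg)
      p <- predictProba(fit$model, test$x)[, "VPC"]
      rep_ <- evaluateScores(p, test$labels, nBoot = nBoot,
                             seed = baseSeed + i)
      row$accuracy <- rep_@metrics[["accuracy"]]
      row$auc <- rep_@auc
      row$sensitivity <- rep_@metrics[["sensitivity"]]
      row$specificity <- rep_@metrics[["specificity"]]
      row
    }, error = function(e) {
      failures <<- c(failures, sprintf("spec %d: %s", i,
                                       conditionMessage(e)))
      row
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Kernel-size sweep for the time-series families
#'
#' Convenience wrapper running [sweepModels()] over [kernelSizeGrid()].
#'
#' @param modes Which families to sweep (`"single"`, `"multi"`).
#' @param sizes Kernel sizes (default 3, 5, 7, 9, 11).
#' @param train,validation,test,config,baseSeed,nBoot See [sweepModels()].
#' @return data.frame with one row per (mode, kernel size).
#' @export
sweepKernels <- function(train, validation, test,
                         modes = c("single", "multi"),
                         sizes = c(3L, 5L, 7L, 9L, 11L),
                         config = trainConfig(), baseSeed = 1L,
                         nBoot = 200L) {
  specs <- unlist(lapply(modes, function(m) kernelSizeGrid(m, sizes)),
                  recursive = FALSE)
  sweepModels(specs, train, validation, test, config, baseSeed, nBoot)
}
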