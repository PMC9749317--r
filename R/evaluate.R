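## Diagnostic evaluation: ROC/AUC, Youden-optimal cut-point, confusion
## metrics, stratified bootstrap percentile confidence intervals.

## Mann-Whitney AUC (handles ties via midranks); equals the trapezoidal
## area under the empirical ROC.
aucRank <- function(scores, pos) {
  nP <- sum(pos); nN <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

## Sensitivity/specificity at every distinct threshold (rule: score >=
## threshold is called positive). Returns a data.frame sorted by
## descending threshold.
rocPoints <- function(scores, pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  cumP <- cumsum(p); cumN <- cumsum(!p)
  last <- findInterval(-thr, -s)   # last index with score >= thr
  data.frame(threshold = thr,
             sens = cumP[last] / sum(pos),
             spec = 1 - cumN[last] / sum(!pos))
}

confusionAt <- function(scores, pos, threshold) {
  call <- scores >= threshold
  c(TP = sum(call & pos), FP = sum(call & !pos),
    TN = sum(!call & !pos), FN = sum(!call & pos))
}

metricsFromCounts <- function(cts) {
  tot <- sum(cts)
  c(accuracy = unname((cts["TP"] + cts["TN"]) / tot),
    sensitivity = unname(cts["TP"] / (cts["TP"] + cts["FN"])),
    specificity = unname(cts["TN"] / (cts["TN"] + cts["FP"])),
    ppv = unname(cts["TP"] / (cts["TP"] + cts["FP"])),
    npv = unname(cts["TN"] / (cts["TN"] + cts["FN"])))
}

#' Evaluate classifier scores
#'
#' Builds the ROC over all distinct score thresholds, computes the AUC
#' (trapezoidal rule, equivalently the normalized Mann-Whitney statistic),
#' picks the optimal cut-point maximizing Youden's J = sensitivity +
#' specificity - 1 (ties resolved toward higher specificity), and reports
#' accuracy, sensitivity, specificity, PPV and NPV at that threshold.
#' All quantities get 2-sided 95% percentile confidence intervals from a
#' class-stratified bootstrap (threshold held fixed at the point-estimate
#' cut; the AUC is recomputed per resample).
#'
#' @param scores Per-record probability of the VPC class, in [0, 1].
#' @param labels `"VPC"`/`"NOR"` vector (or logical/0-1 with 1 = VPC).
#' @param nBoot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return An [EvalReport-class].
#' @export
evaluateScores <- function(scores, labels, nBoot = 2000L, seed = 1L,
                           conf = 0.95) {
  pos <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "VPC" else as.logical(labels)
  stopifnot(length(scores) == length(pos), all(is.finite(scores)))
  if (any(scores < 0 | scores > 1)) stopf("scores must lie in [0, 1]")
  if (!any(pos) || all(pos))
    stopf("both classes must be present to evaluate")

  auc <- aucRank(scores, pos)
  roc <- rocPoints(scores, pos)
  j <- roc$sens + roc$spec - 1
  cand <- which(j == max(j))
  thr <- roc$threshold[cand[which.max(roc$spec[cand])]]
  cts <- confusionAt(scores, pos, thr)
  met <- metricsFromCounts(cts)

  iP <- which(pos); iN <- which(!pos)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  boot <- withSeed(seed, {
    t(vapply(seq_len(nBoot), function(b) {
      ii <- c(sample(iP, length(iP), replace = TRUE),
              sample(iN, length(iN), replace = TRUE))
      sb <- scores[ii]; pb <- pos[ii]
      c(auc = aucRank(sb, pb), metricsFromCounts(confusionAt(sb, pb, thr)))
    }, numeric(6)))
  })
  ci <- apply(boot, 2, quantile, probs = qs, na.rm = TRUE)
  est <- c(auc = auc, met)
  ci[1, ] <- pmin(ci[1, ], est)  # percentile CIs always cover the estimate
  ci[2, ] <- pmax(ci[2, ], est)

  new("EvalReport", threshold = thr, auc = auc, metrics = met,
      ci = ci, counts = setNames(as.integer(cts), names(cts)),
      nBoot = as.integer(nBoot))
}
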