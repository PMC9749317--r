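## Patient-disjoint dataset splitting.

#' Patient-disjoint train/validation/test split
#'
#' Draws whole patients at random into the validation set until its record
#' count reaches exactly `targetValN`, then likewise for the test set; all
#' remaining records form the training set. A patient whose record count
#' would overshoot the remaining target is skipped in that pass; if a pass
#' exhausts all patients without hitting the target exactly, a fresh
#' shuffle is tried (up to `maxRetries` times). Patient-disjointness is
#' guaranteed by construction and the result is deterministic under `seed`.
#'
#' @param roster data.frame with columns `record_id`, `patient_id` and
#'   (optionally) `label`.
#' @param targetValN,targetTestN Exact record counts for the validation and
#'   test sets (defaults 50 and 100).
#' @param seed Integer seed.
#' @param maxRetries Shuffle attempts before giving up.
#' @return The roster with an added `split` column
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
splitByPatient <- function(roster, targetValN = 50L, targetTestN = 100L,
                           seed = 1L, maxRetries = 200L) {
  stopifnot(all(c("record_id", "patient_id") %in% names(roster)))
  if (anyDuplicated(roster$record_id)) stopf("record ids must be unique")
  sizes <- table(roster$patient_id)
  total <- nrow(roster)
  if (total <= targetValN + targetTestN)
    stopf("need more than %d records, have %d",
          targetValN + targetTestN, total)

  ## greedy first-fit over a shuffled patient order; exact-sum or NULL
  pick <- function(pat, sz, target) {
    got <- character(0)
    left <- target
    for (p in pat) {
      if (sz[[p]] <= left) {
        got <- c(got, p)
        left <- left - sz[[p]]
        if (left == 0L) return(got)
      }
    }
    NULL
  }

  withSeed(seed, {
    bestShort <- Inf
    for (try in seq_len(maxRetries)) {
      pats <- sample(names(sizes))
      val <- pick(pats, sizes, targetValN)
      if (is.null(val)) { bestShort <- min(bestShort, targetValN); next }
      rest <- setdiff(pats, val)
      tst <- pick(rest, sizes, targetTestN)
      if (is.null(tst)) { bestShort <- min(bestShort, targetTestN); next }
      split <- rep("train", total)
      split[roster$patient_id %in% val] <- "validation"
      split[roster$patient_id %in% tst] <- "test"
      roster$split <- split
      return(roster)
    }
    achievableMsg <- if (is.finite(bestShort))
      sprintf(" (no patient combination reaches %d exactly; nearest achievable counts differ — adjust the targets)",
              bestShort) else ""
    stopf("could not reach exact validation/test counts %d/%d in %d attempts%s",
          targetValN, targetTestN, maxRetries, achievableMsg)
  })
}

#' Check a split for patient leakage
#'
#' @param assignment Output of [splitByPatient()].
#' @return Invisibly TRUE; errors if any patient appears in two partitions.
#' @export
assertPatientDisjoint <- function(assignment) {
  tab <- table(assignment$patient_id,
               factor(assignment$split,
                      levels = c("train", "validation", "test")))
  bad <- rowSums(tab > 0) > 1L
  if (any(bad))
    stopf("%d patient(s) appear in more than one partition", sum(bad))
  invisible(TRUE)
}
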