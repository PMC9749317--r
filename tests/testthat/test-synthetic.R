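test_that("waveform generator produces 12 leads at rate x duration samples", {
  s <- generateWaveform(waveformParams(), durationS = 2.5, rateHz = 500,
                        seed = 1)
  expect_identical(dim(leadSignals(s)), c(1250L, 12L))
  expect_identical(leadNames(s), vpcECG:::LEAD_NAMES)
  s2 <- generateWaveform(waveformParams(), durationS = 1, rateHz = 100,
                         seed = 1)
  expect_identical(nrow(leadSignals(s2)), 100L)
  expect_error(generateWaveform(waveformParams(), durationS = -1),
               "positive")
  expect_error(generateWaveform(waveformParams(), rateHz = 0), "positive")
})

test_that("waveform generation is deterministic under a seed", {
  p <- waveformParams(noiseSd = 0.05, baselineWanderAmp = 0.1)
  a <- generateWaveform(p, seed = 42)
  b <- generateWaveform(p, seed = 42)
  expect_identical(leadSignals(a), leadSignals(b))
  c_ <- generateWaveform(p, seed = 43)
  expect_false(identical(leadSignals(a), leadSignals(c_)))
})

test_that("zero effect size makes VPC and NOR generators identically distributed", {
  ## permutation test on a per-record summary statistic over 200 draws
  stat <- function(label, seed) {
    p <- waveformParams(classLabel = label, classEffectSize = 0,
                        noiseSd = 0.02)
    sd(leadSignals(generateWaveform(p, seed = seed))[, "II"])
  }
  sv <- vapply(1:100, function(i) stat("VPC", 1000 + i), 1)
  sn <- vapply(1:100, function(i) stat("NOR", 2000 + i), 1)
  obs <- abs(mean(sv) - mean(sn))
  pool <- c(sv, sn)
  set.seed(9)
  perm <- replicate(500, {
    sh <- sample(pool)
    abs(mean(sh[1:100]) - mean(sh[101:200]))
  })
  expect_gt(mean(perm >= obs), 0.01)
  ## and a positive control: the perturbation moves the statistic
  svEff <- vapply(1:100, function(i) {
    p <- waveformParams(classLabel = "VPC", classEffectSize = 1,
                        noiseSd = 0.02)
    sd(leadSignals(generateWaveform(p, seed = 1000 + i))[, "II"])
  }, 1)
  expect_gt(abs(mean(svEff) - mean(sn)), obs + 3 * sd(sn) / sqrt(100))
})

test_that("all-zero signals render as flat baselines", {
  sig <- new("LeadSignalSet",
             signals = matrix(0, 1250, 12,
                              dimnames = list(NULL, vpcECG:::LEAD_NAMES)),
             rateHz = 500)
  rec <- renderEcgImage(sig)
  lay <- rec@image@layout
  for (q in seq_len(lay@nSubimages))
    for (tr in seq_len(lay@tracesPerSubimage))
      expect_true(all(truthRows(rec)[[q]][, tr] ==
                        lay@traceBaselineRows[tr]))
})

test_that("constant amplitude renders at baseline - round(px * a)", {
  a <- 0.73
  sig <- new("LeadSignalSet",
             signals = matrix(a, 1250, 12,
                              dimnames = list(NULL, vpcECG:::LEAD_NAMES)),
             rateHz = 500)
  rec <- renderEcgImage(sig)
  lay <- rec@image@layout
  want <- round(lay@traceBaselineRows[2] - lay@pxPerUnit * a)
  expect_true(all(truthRows(rec)[[1]][, 2] == want))
})

test_that("trace pixel count matches the brute-force rasterization oracle", {
  rec <- quickRecord(seed = 7)
  lay <- rec@image@layout
  H <- lay@imageHeight
  want <- 0L
  cover <- matrix(FALSE, H, lay@nSubimages * lay@columnsPerSubimage)
  for (q in seq_len(lay@nSubimages)) {
    for (tr in seq_len(lay@tracesPerSubimage)) {
      sp <- oracleTraceSpans(truthRows(rec)[[q]][, tr], H)
      for (c_ in seq_len(lay@columnsPerSubimage)) {
        col <- (q - 1L) * lay@columnsPerSubimage + c_
        cover[sp$lo[c_]:sp$hi[c_], col] <- TRUE
      }
    }
  }
  expect_identical(sum(truthMask(rec) == 2L), sum(cover))
})

test_that("excursions beyond the image are clipped and flagged", {
  p <- waveformParams(qrsAmp = 50)  # far outside the trace band
  s <- generateWaveform(p, seed = 1)
  rec <- renderEcgImage(s)
  expect_true(rec@clipped)
  expect_true(all(truthMask(rec) %in% 0:2))
})

test_that("cohort respects forced class counts and record ranges", {
  co <- generateCohort(10, recordsPerPatient = c(1, 1), classBalance = 0.5,
                       seed = 3, materialize = FALSE)
  m <- cohortManifest(co)
  expect_identical(nrow(m), 10L)
  expect_identical(sum(m$label == "VPC"), 5L)
  expect_identical(sum(m$label == "NOR"), 5L)

  co2 <- generateCohort(60, recordsPerPatient = c(1, 4), seed = 4,
                        materialize = FALSE)
  m2 <- cohortManifest(co2)
  expect_true(nrow(m2) >= 60 && nrow(m2) <= 240)
  perPat <- table(m2$patient_id)
  expect_true(all(perPat >= 1 & perPat <= 4))
  ## class proportion of patients within 3 binomial SEs of the target
  pVpc <- mean(tapply(m2$label, m2$patient_id, `[`, 1) == "VPC")
  se <- sqrt(0.5 * 0.5 / 60)
  expect_lt(abs(pVpc - 0.5), 3 * se + 1e-9)
})

test_that("a patient never carries two labels and manifests are reproducible", {
  co <- generateCohort(25, seed = 9, materialize = FALSE)
  m <- cohortManifest(co)
  expect_true(all(tapply(m$label, m$patient_id,
                         function(x) length(unique(x))) == 1L))
  co2 <- generateCohort(25, seed = 9, materialize = FALSE)
  expect_identical(m, cohortManifest(co2))
  ## degenerate class balance is rejected
  expect_error(generateCohort(4, classBalance = 0.01), "class")
})

test_that("cohortRecord regenerates identical records on demand", {
  co <- generateCohort(4, recordsPerPatient = c(1, 2), seed = 5,
                       materialize = TRUE)
  lazy <- generateCohort(4, recordsPerPatient = c(1, 2), seed = 5,
                         materialize = FALSE)
  r1 <- co@records[[2]]
  r2 <- cohortRecord(lazy, 2)
  expect_identical(imagePixels(r1), imagePixels(r2))
  expect_identical(leadSignals(truthSignals(r1)),
                   leadSignals(truthSignals(r2)))
})
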