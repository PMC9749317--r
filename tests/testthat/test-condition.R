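test_that("upsampling maps 250 points to 1250 with exact endpoints", {
  x <- rnorm(250)
  u <- upsampleSeries(x, 500, 2.5)
  expect_length(u, 1250L)
  expect_identical(u[1], x[1])
  expect_identical(u[1250], x[250])
  expect_true(all(upsampleSeries(rep(3.3, 250)) == 3.3))
  ## linear ramp maps to the exact affine ramp
  ramp <- 0:249
  u2 <- upsampleSeries(ramp)
  want <- seq(0, 249, length.out = 1250)
  expect_lt(max(abs(u2 - want)), 1e-9)
  expect_error(upsampleSeries(rnorm(300), 100, 2.5), "never downsamples")
})

test_that("upsampling preserves the input range (no overshoot)", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(250)
    u <- upsampleSeries(x)
    expect_gte(min(u), min(x))
    expect_lte(max(u), max(x))
  }
})

test_that("low-pass filter has unit DC gain", {
  x <- rep(2.5, 1250)
  for (zp in c(TRUE, FALSE)) {
    y <- lowpassFilter(x, filterConfig(zeroPhase = zp), 500)
    expect_lt(max(abs(y / 2.5 - 1)), 1e-6)
  }
})

test_that("filter magnitudes match the analytic Butterworth response", {
  rate <- 500
  t <- (0:4999) / rate
  for (f in c(2, 50)) {
    x <- sin(2 * pi * f * t)
    core <- 1001:4000  # steady state, an integer number of cycles
    y1 <- lowpassFilter(x, filterConfig(zeroPhase = FALSE), rate)
    a1 <- sineAmplitude(y1[core], f, rate)
    ## exact closed form for the realized (bilinear digital) filter
    wantD <- butterMagnitudeDigital(f, 15, 3, rate)
    expect_lt(abs(20 * log10(a1) - 20 * log10(wantD)), 1)
    y2 <- lowpassFilter(x, filterConfig(zeroPhase = TRUE), rate)
    a2 <- sineAmplitude(y2[core], f, rate)
    expect_lt(abs(20 * log10(a2) - 40 * log10(wantD)), 1)
    ## the analog prototype formula agrees up to bilinear warping
    wantA <- butterMagnitude(f, 15, 3)
    expect_lt(abs(20 * log10(wantD) - 20 * log10(wantA)), 1)
  }
  ## passband tone essentially preserved
  x2 <- sin(2 * pi * 2 * t)
  y <- lowpassFilter(x2, filterConfig(), rate)
  expect_lt(abs(sineAmplitude(y[1001:4000], 2, rate) - 1), 0.05)
  expect_error(lowpassFilter(x2, filterConfig(cutoffHz = 300), 500),
               "Nyquist")
})

test_that("stopband attenuation meets the contract", {
  rate <- 500
  t <- (0:2499) / rate
  x <- sin(2 * pi * 50 * t)
  core <- 501:2000  # 150 whole cycles
  aSingle <- sineAmplitude(lowpassFilter(x, filterConfig(zeroPhase = FALSE),
                                         rate)[core], 50, rate)
  expect_gte(-20 * log10(aSingle), 25)
  aZero <- sineAmplitude(lowpassFilter(x, filterConfig(zeroPhase = TRUE),
                                       rate)[core], 50, rate)
  expect_gte(-20 * log10(aZero), 50)
})

test_that("normalization is min-max to [0,1] with the constant-lead policy", {
  expect_equal(normalizeLeads(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalizeLeads(rep(4, 7)), rep(0.5, 7))
  set.seed(1)
  x <- rnorm(200)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(normalizeLeads(a * x + b), normalizeLeads(x))
  }
  n1 <- normalizeLeads(x)
  expect_equal(normalizeLeads(n1), n1)   # idempotent
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("digitization produces a 1250 x 12 tensor deterministically", {
  rec <- quickRecord(seed = 21)
  st <- digitizeEcg(rec@image)
  expect_identical(dim(tensorValues(st)), c(1250L, 12L))
  expect_identical(leadNames(st), vpcECG:::LEAD_NAMES)
  st2 <- digitizeEcg(rec@image)
  expect_identical(tensorValues(st), tensorValues(st2))
})

test_that("digitized tensors match the conditioned ground truth", {
  rec <- quickRecord(seed = 22)
  st <- digitizeEcg(rec@image)
  truth <- normalizeLeads(lowpassFilter(leadSignals(truthSignals(rec)),
                                        filterConfig(), 500))
  for (lead in vpcECG:::LEAD_NAMES)
    expect_gte(cor(tensorValues(st)[, lead], truth[, lead]), 0.98)
})

test_that("stage failures carry the stage name", {
  blank <- new("EcgImage",
               pixels = array(255L, dim = c(50, 1000, 3)),
               layout = standardLeadLayout(), sourceId = "blank")
  expect_error(digitizeEcg(blank), "crop_to_signal")
})
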