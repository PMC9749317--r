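test_that("image model head has the specified dense widths", {
  m <- buildImageModel(imageModelSpec("TINY", denseSize = 512L), seed = 1)
  s <- modelSummary(m)
  dense <- s[grepl("^dense", s$layer), ]
  expect_identical(dense$output, c("512", "2"))
  expect_true(any(s$layer == "dropout(0.50)"))
  expect_true(any(s$layer == "gap"))
})

test_that("unknown backbones are rejected with the registry listed", {
  expect_error(imageModelSpec("ResNet9000"), "VGG16.*Xception|registry")
})

test_that("every registry backbone forwards to a softmax pair", {
  set.seed(1)
  x <- list(array(runif(256 * 512 * 3), c(256, 512, 3)))
  for (id in c("TINY", "VGG16", "ResNet50V2", "InceptionV3",
               "InceptionResNetV2", "Xception")) {
    m <- buildImageModel(imageModelSpec(id), seed = 2)
    p <- predictProba(m, x)
    expect_identical(dim(p), c(1L, 2L))
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-6)
  }
})

test_that("TINY parameter count equals the closed-form layer sum", {
  m <- buildImageModel(imageModelSpec("TINY", denseSize = 512L), seed = 3)
  conv <- function(k, cin, f) k * k * cin * f + f
  bn <- function(f) 2 * f
  dense <- function(i, o) i * o + o
  want <- conv(5, 3, 8) + bn(8) + conv(3, 8, 16) + bn(16) +
    conv(3, 16, 32) + bn(32) + dense(32, 512) + dense(512, 2)
  expect_identical(countParams(m), want)
})

test_that("conv block output lengths follow the closed-form arithmetic", {
  for (k in c(3L, 5L, 7L, 9L, 11L)) {
    m <- buildTsModel(tsModelSpec("single", k), seed = 1)
    s <- modelSummary(m)
    convLen <- as.integer(sub("x.*", "", s$output[grepl("^conv1d",
                                                        s$layer)]))
    poolLen <- as.integer(sub("x.*", "", s$output[grepl("^maxpool",
                                                        s$layer)]))
    ## first block against the closed form on 1250 samples
    expect_identical(convLen[1], oracleConvLen(1250L, k, 3L))
    expect_identical(poolLen[1], oracleConvLen(convLen[1], 5L, 3L))
    ## all later blocks chain the same formulas
    L <- 1250L
    ci <- 0L; pi_ <- 0L
    repeat {
      if (L < k) break
      ci <- ci + 1L
      L <- oracleConvLen(L, k, 3L)
      expect_identical(convLen[ci], L)
      if (L >= 5L) {
        pi_ <- pi_ + 1L
        L <- oracleConvLen(L, 5L, 3L)
        expect_identical(poolLen[pi_], L)
      }
      if (ci >= length(convLen)) break
    }
  }
})

test_that("time-series models output softmax pairs for both modes", {
  x <- list(matrix(rnorm(1250 * 12), 1250, 12))
  for (mode in c("single", "multi")) {
    m <- buildTsModel(tsModelSpec(mode), seed = 4)
    p <- predictProba(m, x)
    expect_lt(abs(sum(p) - 1), 1e-6)
  }
})

test_that("the multi-input model keeps 12 weight-independent lead branches", {
  m <- buildTsModel(tsModelSpec("multi", 11L), seed = 5)
  expect_identical(m@spec$nLeads, 12L)
  g1 <- m@net$layers[[1]]
  expect_identical(g1$kind, "gconv1d")
  expect_identical(g1$groups, 12L)
  expect_identical(dim(g1$W)[1], 11L)  # (k x 1 lead) taps per branch
  ## branches are initialized independently
  expect_false(isTRUE(all.equal(g1$W[, , 1], g1$W[, , 2])))
  m2 <- buildTsModel(tsModelSpec("multi", 11L), seed = 6)
  expect_false(isTRUE(all.equal(g1$W, m2@net$layers[[1]]$W)))
  ## a grouped conv equals a hand-computed per-lead conv
  xm <- matrix(rnorm(1250 * 12), 1250, 12)
  fw <- vpcECG:::nnForward(g1, vpcECG:::tens1d(xm, 1L, 1250L), FALSE)
  g <- 5L; k <- 11L; f <- g1$filters
  L2 <- (1250L - k) %/% 3L + 1L
  Xc <- sapply(0:(k - 1), function(t) xm[(seq_len(L2) - 1L) * 3L + t + 1L,
                                         g])
  zman <- Xc %*% g1$W[, , g] + rep(g1$b[, g], each = L2)
  expect_equal(fw$out$x[, (g - 1L) * f + seq_len(f)], zman,
               ignore_attr = TRUE)
})

test_that("the single-input head uses dropout and the multi head does not", {
  s1 <- modelSummary(buildTsModel(tsModelSpec("single"), seed = 1))
  expect_true(any(grepl("dropout", s1$layer)))
  s2 <- modelSummary(buildTsModel(tsModelSpec("multi"), seed = 1))
  expect_false(any(grepl("dropout", s2$layer)))
})

test_that("kernel grids enumerate specs differing only in kernel size", {
  g <- kernelSizeGrid("single", c(3, 5, 7, 9, 11))
  expect_length(g, 5L)
  one <- kernelSizeGrid("single", 7)
  expect_identical(one[[1]], tsModelSpec("single", 7L))
  base <- g[[1]]
  for (sp in g[-1]) {
    d <- setdiff(names(base), "kernelSize")
    expect_identical(sp[d], base[d])
  }
  expect_warning(tsModelSpec("single", 13L), "sweep")
})

test_that("inference forward passes are deterministic", {
  m <- buildTsModel(tsModelSpec("single"), seed = 7)
  x <- list(matrix(rnorm(1250 * 12), 1250, 12))
  expect_identical(predictProba(m, x), predictProba(m, x))
})
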