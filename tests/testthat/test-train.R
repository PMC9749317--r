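## A tiny, fast ts spec used throughout the training tests.
tinyTsSpec <- function(k = 5L)
  tsModelSpec("single", k, filters = c(8L, 16L), inputLen = 100L)

toyData <- function(n = 8, sep = 3, seed = 1) {
  set.seed(seed)
  labels <- rep(c("VPC", "NOR"), length.out = n)
  x <- lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(100 * 12, sd = 0.3), 100, 12)
    if (labels[i] == "VPC") base[40:60, ] <- base[40:60, ] + sep
    base
  })
  list(x = x, labels = labels, patients = sprintf("P%02d", seq_len(n)))
}

test_that("a small model overfits separable toy data to accuracy 1", {
  d <- toyData()
  m <- buildTsModel(tinyTsSpec(), seed = 1)
  fit <- trainModel(m, d, config = trainConfig(epochs = 200, patience = 200,
                                               batchSize = 4, seed = 2))
  expect_equal(tail(fit$history$acc, 1), 1)
  p <- predictProba(fit$model, d$x)[, "VPC"]
  expect_true(all((p > 0.5) == (d$labels == "VPC")))
})

test_that("zero patience stops at the first non-improving epoch", {
  d <- toyData()
  m <- buildTsModel(tinyTsSpec(), seed = 3)
  fit <- trainModel(m, d, config = trainConfig(epochs = 50, patience = 0,
                                               batchSize = 4, seed = 4))
  h <- fit$history$loss
  n <- length(h)
  expect_lt(n, 50L)                      # stopped early
  if (n > 2) expect_true(all(diff(h[seq_len(n - 1)]) < 0))
  expect_gte(h[n], h[n - 1])             # the offending epoch
})

test_that("training histories are identical for identical seeds", {
  d <- toyData()
  cfg <- trainConfig(epochs = 5, patience = 5, batchSize = 4, seed = 9)
  f1 <- trainModel(buildTsModel(tinyTsSpec(), seed = 5), d, config = cfg)
  f2 <- trainModel(buildTsModel(tinyTsSpec(), seed = 5), d, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(predictProba(f1$model, d$x),
                   predictProba(f2$model, d$x))
})

test_that("early stopping restores the best-validation weights", {
  d <- toyData(n = 12)
  v <- toyData(n = 6, seed = 2)
  v$patients <- sprintf("Q%02d", seq_len(6))
  fit <- trainModel(buildTsModel(tinyTsSpec(), seed = 6), d, v,
                    config = trainConfig(epochs = 30, patience = 4,
                                         batchSize = 4, seed = 7))
  best <- attr(fit$history, "best_epoch")
  expect_identical(fit$history$val_loss[best], min(fit$history$val_loss))
})

test_that("empty datasets and patient leakage are rejected", {
  d <- toyData()
  m <- buildTsModel(tinyTsSpec(), seed = 8)
  expect_error(trainModel(m, list(x = list(), labels = character(0))),
               "empty")
  leaky <- toyData()
  leaky$patients <- d$patients   # same patients in train and validation
  expect_error(trainModel(m, d, leaky, trainConfig(epochs = 1)),
               "leakage")
})

test_that("a singleton sweep matches a direct train + evaluate call", {
  d <- toyData(n = 12)
  v <- toyData(n = 6, seed = 21)
  v$patients <- sprintf("Q%02d", seq_len(6))
  te <- toyData(n = 10, seed = 22)
  te$patients <- sprintf("S%02d", seq_len(10))
  cfg <- trainConfig(epochs = 8, patience = 8, batchSize = 4, seed = 3)
  tab <- sweepModels(list(tinyTsSpec(5L)), d, v, te, config = cfg,
                     baseSeed = 10, nBoot = 50)
  expect_identical(nrow(tab), 1L)
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1L
  fit <- trainModel(buildTsModel(tinyTsSpec(5L), seed = 11), d, v, cfg1)
  p <- predictProba(fit$model, te$x)[, "VPC"]
  r <- evaluateScores(p, te$labels, nBoot = 50, seed = 11)
  expect_equal(tab$auc, r@auc)
  expect_equal(tab$accuracy, r@metrics[["accuracy"]])
})

test_that("sweeps enumerate the kernel grid and survive per-cell failures", {
  d <- toyData(n = 8)
  v <- toyData(n = 4, seed = 31)
  v$patients <- sprintf("Q%02d", seq_len(4))
  te <- toyData(n = 6, seed = 32)
  te$patients <- sprintf("S%02d", seq_len(6))
  cfg <- trainConfig(epochs = 2, patience = 2, batchSize = 4, seed = 1)
  specs <- kernelSizeGrid("single", c(3L, 5L), filters = c(8L, 16L),
                          inputLen = 100L)
  broken <- tinyTsSpec(5L); broken$filters <- c(-1L, -1L)  # will not build
  tab <- sweepModels(c(specs, list(broken)), d, v, te, config = cfg,
                     nBoot = 20)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$kernel_size[1:2], c(3L, 5L))
  expect_false(anyNA(tab$auc[1:2]))
  expect_true(is.na(tab$auc[3]))
  expect_length(attr(tab, "failures"), 1L)
})
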