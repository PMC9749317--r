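test_that("perfect separation yields AUC 1 and a threshold between classes", {
  scores <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.15)
  labels <- c("VPC", "VPC", "VPC", "NOR", "NOR", "NOR")
  r <- evaluateScores(scores, labels, nBoot = 100, seed = 1)
  expect_equal(r@auc, 1)
  expect_equal(r@metrics[["accuracy"]], 1)
  expect_gt(r@threshold, 0.2)
  expect_lte(r@threshold, 0.8)
})

test_that("the worked four-record example gives AUC 0.75", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.3, 0.5, 0.1)
  expect_equal(oracleAUC(scores, labels == 1), 0.75)  # 3 of 4 pairs
  r <- evaluateScores(scores, labels, nBoot = 100, seed = 1)
  expect_equal(r@auc, 0.75)
})

test_that("AUC equals the concordant-pair oracle and Youden the brute force", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # provoke ties
    r <- evaluateScores(scores, ifelse(pos, "VPC", "NOR"), nBoot = 10,
                        seed = i)
    expect_equal(r@auc, oracleAUC(scores, pos))
    o <- oracleYouden(scores, pos)
    expect_equal(r@threshold, o$thr)
    expect_equal(r@metrics[["sensitivity"]], o$sens)
    expect_equal(r@metrics[["specificity"]], o$spec)
  }
})

test_that("AUC and cut-point agree with pROC on reference cases", {
  skip_if_not_installed("pROC")
  set.seed(202)
  for (i in 1:5) {
    n <- 80
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(pos) || all(pos)) next
    scores <- pmin(pmax(rnorm(n, ifelse(pos, 0.6, 0.4), 0.2), 0), 1)
    r <- evaluateScores(scores, ifelse(pos, "VPC", "NOR"), nBoot = 10,
                        seed = i)
    proc <- pROC::roc(pos, scores, quiet = TRUE, direction = "<")
    expect_equal(r@auc, as.numeric(pROC::auc(proc)))
    co <- pROC::coords(proc, "best", best.method = "youden",
                       transpose = FALSE)
    ## same maximal J even if the tie-break picks a different threshold
    expect_equal(r@metrics[["sensitivity"]] + r@metrics[["specificity"]],
                 max(co$sensitivity + co$specificity), tolerance = 1e-9)
  }
})

test_that("random scores on balanced labels give AUC near 0.5", {
  set.seed(303)
  n <- 2000
  labels <- rep(c("VPC", "NOR"), n / 2)
  scores <- runif(n)
  r <- evaluateScores(scores, labels, nBoot = 10, seed = 1)
  expect_lt(abs(r@auc - 0.5), 0.03)
})

test_that("evaluation is invariant under monotone score transforms", {
  set.seed(404)
  pos <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  pos[1:2] <- c(TRUE, FALSE)
  scores <- runif(60)
  r1 <- evaluateScores(scores, ifelse(pos, "VPC", "NOR"), nBoot = 10,
                       seed = 2)
  tr <- plogis(3 * qlogis(pmin(pmax(scores, 1e-6), 1 - 1e-6)))
  r2 <- evaluateScores(tr, ifelse(pos, "VPC", "NOR"), nBoot = 10, seed = 2)
  expect_equal(r1@auc, r2@auc)
  expect_identical(r1@counts, r2@counts)
})

test_that("confidence intervals cover their estimates and inputs are checked", {
  set.seed(505)
  pos <- rep(c(TRUE, FALSE), each = 40)
  scores <- pmin(pmax(rnorm(80, ifelse(pos, 0.7, 0.3), 0.15), 0), 1)
  r <- evaluateScores(scores, ifelse(pos, "VPC", "NOR"), nBoot = 500,
                      seed = 3)
  est <- c(auc = r@auc, r@metrics)
  for (nm in names(est)) {
    expect_lte(r@ci[1, nm], est[[nm]])
    expect_gte(r@ci[2, nm], est[[nm]])
  }
  expect_identical(sum(r@counts), 80L)
  expect_error(evaluateScores(rep(0.5, 4), c("VPC", "VPC", "VPC", "VPC")),
               "both classes")
  expect_error(evaluateScores(c(-0.1, 0.5), c("VPC", "NOR")), "\\[0, 1\\]")
})
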