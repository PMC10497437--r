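test_that("AUC on small hand-checked instances", {
  # perfectly separated groups
  expect_equal(auc(rocAnalysis(c(5, 6, 1, 2), c(1, 1, 0, 0))), 1.0)
  # positives {2,4} vs negatives {1,3}: 3 of 4 pairs concordant
  expect_equal(auc(rocAnalysis(c(2, 4, 1, 3), c(1, 1, 0, 0))), 0.75)
  # identically distributed groups
  expect_equal(auc(rocAnalysis(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0))), 0.5)
})

test_that("single-class labels are rejected", {
  expect_error(rocAnalysis(c(1, 2), c(1, 1)), class = "inputError")
})

test_that("sensitivity is nonincreasing and specificity nondecreasing in the threshold", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    scores <- sample(1:8, n, replace = TRUE)      # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- rocAnalysis(scores, labels)
    df <- as.data.frame(roc)
    expect_true(all(diff(df$sensitivity) <= 1e-12))
    expect_true(all(diff(df$specificity) >= -1e-12))
  }
})

test_that("AUC equals midrank U/(n1 n0) and complements under score negation", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    scores <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- rocAnalysis(scores, labels)
    # independent midrank U
    r <- rank(scores); n1 <- sum(labels); n0 <- n - n1
    aucU <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(auc(roc), aucU, tolerance = 1e-12)
    expect_equal(auc(roc) + auc(rocAnalysis(-scores, labels)), 1,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:10) {
    n <- 30
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(auc(rocAnalysis(scores, labels)), ref, tolerance = 1e-12)
  }
})

test_that("Youden cutoffs surface all co-optimal thresholds", {
  roc <- rocAnalysis(c(2, 4, 1, 3), c(1, 1, 0, 0))
  yc <- youdenCutoffs(roc)
  expect_equal(yc$threshold, c(2, 4))            # both attain J = 0.5
  expect_equal(yc$youden_j, c(0.5, 0.5))
  # perfect separation: the single separating threshold attains J = 1
  yp <- youdenCutoffs(rocAnalysis(c(5, 6, 1, 2), c(1, 1, 0, 0)))
  expect_equal(nrow(yp), 1)
  expect_equal(yp$threshold, 5)
  expect_equal(yp$youden_j, 1)
})

test_that("Youden and top-left equal exhaustive search over all thresholds", {
  set.seed(47)
  for (i in 1:30) {
    n <- sample(8:25, 1)
    scores <- sample(seq(0, 10, 0.5), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- rocAnalysis(scores, labels)
    df <- as.data.frame(roc)
    j <- df$sensitivity + df$specificity - 1
    bestJ <- df$threshold[j >= max(j) - 1e-12]
    expect_equal(youdenCutoffs(roc)$threshold, sort(bestJ))
    d <- sqrt((1 - df$sensitivity)^2 + (1 - df$specificity)^2)
    ties <- df$threshold[d <= min(d) + 1e-12]
    expect_equal(closestTopLeftCutoff(roc)$threshold, min(ties))
  }
})

test_that("degenerate all-equal scores yield a defined single cutoff", {
  roc <- rocAnalysis(rep(5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(auc(roc), 0.5)
  tl <- closestTopLeftCutoff(roc)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$threshold, 5)                  # smaller threshold on tie
})

test_that("direction='less' orients low scores as positive", {
  roc <- rocAnalysis(c(1, 2, 5, 6), c(1, 1, 0, 0), direction = "less")
  expect_equal(auc(roc), 1.0)
})
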