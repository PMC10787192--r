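test_that("one-sided Mann-Whitney matches exhaustive enumeration", {
  mw <- mannWhitneyOneSided(c(3, 4), c(1, 2))
  expect_equal(mw$U, 4)
  expect_equal(mw$p, 1 / 6)
  expect_equal(mannWhitneyOneSided(2, 1)$p, 0.5)
  expect_equal(mannWhitneyOneSided(c(1, 2), c(3, 4))$p, 1.0)
  set.seed(51)
  for (rep in 1:10) {
    r <- rnorm(3); s <- rnorm(4)
    expect_equal(mannWhitneyOneSided(r, s)$p, mwEnumerate(r, s),
                 tolerance = 1e-12)
  }
  expect_error(mannWhitneyOneSided(numeric(), 1), "non-empty")
})

test_that("exact and normal-approximation paths agree closely at n = 6 + 6", {
  set.seed(52)
  for (rep in 1:100) {
    r <- rnorm(6); s <- rnorm(6)
    pExact <- suppressWarnings(
      wilcox.test(r, s, alternative = "greater", exact = TRUE))$p.value
    pApprox <- suppressWarnings(
      wilcox.test(r, s, alternative = "greater", exact = FALSE,
                  correct = TRUE))$p.value
    expect_lt(abs(pExact - pApprox), 0.02)
    expect_equal(mannWhitneyOneSided(r, s)$p, pExact, tolerance = 1e-12)
  }
})

test_that("Fisher's combined probability matches closed-form chi-square", {
  expect_equal(fisherCombined(c(1, 1))$p, 1.0)
  expect_equal(fisherCombined(0.05)$p, 0.05, tolerance = 1e-12)
  X <- -2 * sum(log(c(0.1, 0.1)))
  expect_equal(fisherCombined(c(0.1, 0.1))$p, (1 + X / 2) * exp(-X / 2),
               tolerance = 1e-10)
  expect_error(fisherCombined(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisherCombined(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("precision at the k-th percentile counts strict-below calls", {
  pr <- precisionAtPercentile(c(1, 2, 3, 4), c("sensitive", "sensitive",
                                               "resistant", "resistant"),
                              k = 50)
  expect_equal(pr$t_k, 2.5)
  expect_equal(pr$TP, 2); expect_equal(pr$FP, 0)
  expect_equal(pr$precision, 1.0)
  allR <- precisionAtPercentile(1:10, rep("resistant", 10), 30)
  expect_equal(allR$precision, 0)
  allS <- precisionAtPercentile(1:10, rep("sensitive", 10), 30)
  expect_equal(allS$precision, 1)
  expect_error(precisionAtPercentile(1:4, rep("sensitive", 4), 60), "50")
  expect_error(precisionAtPercentile(1:4, rep("sensitive", 4), 0), "50")
  # brute-force counting oracle on random data
  set.seed(53)
  preds <- rnorm(25)
  labels <- sample(c("sensitive", "resistant"), 25, replace = TRUE)
  for (k in c(10, 25, 50)) {
    pr <- precisionAtPercentile(preds, labels, k)
    tk <- quantile(preds, k / 100)
    expect_equal(pr$TP, sum(preds < tk & labels == "sensitive"))
    expect_equal(pr$FP, sum(preds < tk & labels == "resistant"))
  }
})

test_that("AUROC matches pairwise counting and the U-statistic identity", {
  labs <- c("sensitive", "sensitive", "resistant", "resistant")
  expect_equal(aurocScore(c(1, 2, 3, 4), labs), 1.0)   # perfect ordering
  expect_equal(aurocScore(c(4, 3, 2, 1), labs), 0.0)   # reversed
  expect_equal(aurocScore(c(1, 2, 3, 4),
                          c("sensitive", "resistant", "sensitive",
                            "resistant")), 0.75)
  set.seed(54)
  preds <- sample(1:8, 20, replace = TRUE)  # ties on purpose
  labels <- sample(c("sensitive", "resistant"), 20, replace = TRUE,
                   prob = c(0.4, 0.6))
  a <- aurocScore(preds, labels)
  ps <- preds[labels == "sensitive"]; pr <- preds[labels == "resistant"]
  pairs <- outer(ps, pr, function(x, y) (x < y) + 0.5 * (x == y))
  expect_equal(a, mean(pairs), tolerance = 1e-12)
  U <- mannWhitneyOneSided(pr, ps)$U
  expect_equal(a, U / (length(ps) * length(pr)), tolerance = 1e-10)
  expect_error(aurocScore(1:3, rep("sensitive", 3)), "both classes")
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  preds <- rnorm(40)
  labels <- sample(c("sensitive", "resistant"), 40, replace = TRUE)
  ours <- aurocScore(preds, labels)
  ref <- as.numeric(suppressMessages(
    pROC::auc(response = labels, predictor = preds,
              levels = c("resistant", "sensitive"), direction = ">")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Ward merge distance equals the within-cluster ESS increase", {
  # two singletons at Euclidean distance 2
  expect_equal(domainDistance(matrix(c(0, 0), 1), matrix(c(2, 0), 1)), 2)
  expect_equal(domainDistance(matrix(1:4, 2), matrix(1:4, 2)), 0)
  set.seed(56)
  A <- matrix(rnorm(30), 10, 3)
  B <- matrix(rnorm(24, mean = 1), 8, 3)
  ess <- function(M) sum(sweep(M, 2, colMeans(M))^2)
  expect_equal(domainDistance(A, B), ess(rbind(A, B)) - ess(A) - ess(B),
               tolerance = 1e-10)
  shift <- matrix(5, 1, 3)
  expect_equal(domainDistance(A + shift[rep(1, 10), ],
                              B + shift[rep(1, 8), ]),
               domainDistance(A, B), tolerance = 1e-10)
  expect_error(domainDistance(A, B[, 1:2]), "widths differ")
  # per-member form reports mean and percentile interval
  dm <- domainDistance(list(A, A + 1), list(B, B))
  expect_length(dm$perMember, 2)
  expect_equal(dm$mean, mean(dm$perMember))
})

test_that("the transfer report bundles the statistics coherently", {
  set.seed(57)
  preds <- c(rnorm(12, -1), rnorm(10, 1))
  labels <- c(rep("sensitive", 12), rep("resistant", 10))
  rep <- evaluateTransfer(preds, labels, percentiles = c(10, 25, 50),
                          drug = "tam")
  expect_s3_class(rep, "evalReport")
  expect_equal(rep$auroc, aurocScore(preds, labels))
  expect_true(rep$p > 0 && rep$p <= 1)
  expect_identical(nrow(rep$precision), 3L)
  expect_true(all(rep$precision$TP + rep$precision$FP ==
                    vapply(rep$precision$t_k,
                           function(t) sum(preds < t), numeric(1))))
})
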