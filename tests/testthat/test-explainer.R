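test_that("masking contributions match the hand-computed two-gene example", {
  # transparent model yhat = x1 + x2 built from ReLU-safe identity weights
  model <- handPredictor(list(diag(2), matrix(1, 2, 1)),
                         list(c(0, 0), 0), c("g1", "g2"))
  X <- matrix(c(1, 1), 1, 2, dimnames = list("s1", c("g1", "g2")))
  ct <- grangerContributions(model, X, y = 2)
  expect_equal(unname(ct@omega[1, ]), c(0.5, 0.5))
  expect_equal(ct@eps, 0)
})

test_that("a gene the predictor ignores receives zero contribution", {
  # weights route g1, g2 through; g3 has an all-zero path
  W1 <- rbind(diag(2), c(0, 0))
  model <- handPredictor(list(W1, matrix(c(1, -2), 2, 1)),
                         list(c(0, 0), 0), c("g1", "g2", "g3"))
  X <- matrix(runif(15, 0.5, 2), 5, 3,
              dimnames = list(paste0("s", 1:5), c("g1", "g2", "g3")))
  y <- predictResponse(model, X) + 1   # nonzero baseline error
  ct <- grangerContributions(model, X, y)
  expect_equal(unname(ct@omega[, "g3"]), rep(0, 5))
})

test_that("contribution targets match a symbolic oracle on linear models", {
  set.seed(21)
  for (rep in 1:5) {
    p <- sample(3:8, 1)
    n <- 15
    w <- rnorm(p)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% w) + rnorm(n, 0, 0.5)
    ct <- grangerContributions(function(M) drop(M %*% w), X, y)
    yhat <- drop(X %*% w)
    eps <- (y - yhat)^2
    delta <- sapply(seq_len(p), function(i)
      (y - (yhat - X[, i] * w[i]))^2 - eps)   # masking gene i symbolically
    delta[delta < 0] <- 0
    oracle <- delta / rowSums(delta)
    expect_equal(unname(ct@omega), unname(oracle), tolerance = 1e-8)
  }
})

test_that("degenerate cases: single gene and constant predictor", {
  X1 <- matrix(rnorm(4), 4, 1, dimnames = list(paste0("s", 1:4), "g1"))
  ct1 <- grangerContributions(function(M) drop(M) * 2, X1, rnorm(4))
  expect_equal(unname(ct1@omega[, 1]), rep(1, 4))
  # constant predictor: every mask leaves the error unchanged -> uniform
  X <- matrix(rnorm(12), 4, 3)
  expect_message(
    ct <- grangerContributions(function(M) rep(1, nrow(M)), X, rnorm(4)),
    "uniform")
  expect_true(all(ct@uniformFallback))
  expect_equal(unname(ct@omega), matrix(1 / 3, 4, 3))
})

test_that("contribution vectors always lie on the probability simplex", {
  nz <- sharedNormalized()
  ct <- grangerContributions(sharedModel(), nz$source, nz$y)
  expect_true(all(ct@omega >= 0))
  expect_equal(unname(rowSums(ct@omega)), rep(1, nrow(ct@omega)), tolerance = 1e-8)
})

test_that("explainer distillation recovers a constant target vector", {
  set.seed(31)
  n <- 60; p <- 6L
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(p))))
  v <- c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)
  targets <- matrix(v, n, p, byrow = TRUE, dimnames = dimnames(X))
  ex <- trainExplainer(model = NULL, x = X, y = NULL, nExplainers = 2,
                       hidden = 32, layers = 2, epochs = 250, lr = 5e-3,
                       batchSize = 20, baseSeed = 3, targets = targets)
  Xnew <- matrix(rnorm(20 * p), 20, p,
                 dimnames = list(paste0("t", 1:20), colnames(X)))
  sc <- scoreSamples(ex, Xnew)
  tv <- 0.5 * rowSums(abs(sweep(sc@omega, 2, v)))
  expect_lt(mean(tv), 0.05)
  # output dimensionality equals input dimensionality
  expect_identical(ncol(sc@omega), p)
  # duplicated samples score identically
  Xdup <- Xnew[c(1, 1), ]
  rownames(Xdup) <- c("a", "b")
  sd2 <- scoreSamples(ex, Xdup)
  expect_equal(unname(sd2@omega[1, ]), unname(sd2@omega[2, ]),
               tolerance = 1e-15)
})

test_that("median aggregation of identical explainers equals one member", {
  nz <- sharedNormalized()
  ex <- trainExplainer(model = NULL, x = exprValues(nz$source), y = NULL,
                       nExplainers = 1, hidden = 16, layers = 2, epochs = 20,
                       batchSize = 16, baseSeed = 4,
                       targets = {
                         p <- length(geneIds(nz$source))
                         n <- length(sampleIds(nz$source))
                         m <- matrix(runif(n * p), n, p)
                         m / rowSums(m)
                       })
  trip <- methods::new("ExplainerEnsemble",
                       members = rep(ex@members, 3), geneIds = ex@geneIds,
                       hidden = ex@hidden, nLayers = ex@nLayers)
  X <- exprValues(nz$target)
  expect_equal(scoreSamples(trip, X)@omega, scoreSamples(ex, X)@omega,
               tolerance = 1e-12)
})

test_that("score aggregation averages then rescales to a unit maximum", {
  om <- rbind(s1 = c(0.2, 0.8), s2 = c(0.4, 0.6))
  cs <- methods::new("ContributionSet", omega = om, eps = numeric(),
                     geneIds = c("g1", "g2"), sampleIds = c("s1", "s2"),
                     type = "predicted", uniformFallback = c(FALSE, FALSE))
  ag <- aggregateScores(cs, drug = "d")
  expect_equal(ag@score, c(0.3 / 0.7, 1.0))
  # single sample: its own vector scaled to max 1
  ag1 <- aggregateScores(cs, labeledSampleIds = "s1")
  expect_equal(ag1@score, c(0.25, 1.0))
  # all genes equal: every aggregated score is 1
  omU <- matrix(0.5, 2, 2, dimnames = list(c("s1", "s2"), NULL))
  csU <- methods::new("ContributionSet", omega = omU, eps = numeric(),
                      geneIds = c("g1", "g2"), sampleIds = c("s1", "s2"),
                      type = "predicted", uniformFallback = c(FALSE, FALSE))
  expect_equal(aggregateScores(csU)@score, c(1, 1))
  expect_error(aggregateScores(cs, labeledSampleIds = character()), "empty")
  expect_error(aggregateScores(cs, labeledSampleIds = "nope"), "absent")
})
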