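# The compiled network core: forward pass against a plain-R oracle,
# analytic gradients against finite differences, determinism, convergence.

rForward <- function(W, b, X, softmax = FALSE) {
  A <- X
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% W[[l]], 2, b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  if (softmax) {
    E <- exp(A - apply(A, 1, max))
    A <- E / rowSums(E)
  }
  A
}

randomNet <- function(sizes, seed) drtransfer:::.nn_init(sizes, seed)

test_that("compiled forward pass matches a plain-R reimplementation", {
  set.seed(1)
  net <- randomNet(c(5L, 7L, 4L, 3L), seed = 3L)
  X <- matrix(rnorm(40), 8, 5)
  expect_equal(drtransfer:::.nn_forward(net$weights, net$biases, X, 0L),
               rForward(net$weights, net$biases, X), tolerance = 1e-12)
  sm <- drtransfer:::.nn_forward(net$weights, net$biases, X, 1L)
  expect_equal(sm, rForward(net$weights, net$biases, X, softmax = TRUE),
               tolerance = 1e-12)
  expect_equal(rowSums(sm), rep(1, 8), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  for (outType in c(0L, 1L)) {
    set.seed(10 + outType)
    sizes <- c(4L, 6L, if (outType == 1L) 3L else 1L)
    net <- randomNet(sizes, seed = 11L + outType)
    X <- matrix(rnorm(20), 5, 4)
    Y <- if (outType == 1L) {
      raw <- matrix(runif(15), 5, 3)
      raw / rowSums(raw)
    } else matrix(rnorm(5), 5, 1)
    g <- drtransfer:::.nn_loss_grad(net$weights, net$biases, X, Y, outType)
    h <- 1e-6
    for (l in seq_along(net$weights)) {
      for (idx in sample(length(net$weights[[l]]), 4)) {
        wp <- net$weights; wp[[l]][idx] <- wp[[l]][idx] + h
        wm <- net$weights; wm[[l]][idx] <- wm[[l]][idx] - h
        lp <- drtransfer:::.nn_loss_grad(wp, net$biases, X, Y, outType)$loss
        lm <- drtransfer:::.nn_loss_grad(wm, net$biases, X, Y, outType)$loss
        expect_equal(g$gradWeights[[l]][idx], (lp - lm) / (2 * h),
                     tolerance = 1e-4)
      }
      bp <- net$biases; bp[[l]][1] <- bp[[l]][1] + h
      bm <- net$biases; bm[[l]][1] <- bm[[l]][1] - h
      lp <- drtransfer:::.nn_loss_grad(net$weights, bp, X, Y, outType)$loss
      lm <- drtransfer:::.nn_loss_grad(net$weights, bm, X, Y, outType)$loss
      expect_equal(g$gradBiases[[l]][1], (lp - lm) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic given the seed and reduces the loss", {
  set.seed(2)
  X <- matrix(rnorm(300), 50, 6)
  y <- cbind(X %*% rnorm(6) + rnorm(50, 0, 0.1))
  f1 <- drtransfer:::trainDenseNet(X, y, hidden = c(16, 8), dropout = 0.2,
                                   lr = 1e-3, batchSize = 10, epochs = 50,
                                   seed = 9L)
  f2 <- drtransfer:::trainDenseNet(X, y, hidden = c(16, 8), dropout = 0.2,
                                   lr = 1e-3, batchSize = 10, epochs = 50,
                                   seed = 9L)
  expect_identical(f1$weights, f2$weights)
  f3 <- drtransfer:::trainDenseNet(X, y, hidden = c(16, 8), dropout = 0.2,
                                   lr = 1e-3, batchSize = 10, epochs = 50,
                                   seed = 10L)
  expect_false(identical(f1$weights, f3$weights))
  loss <- f1$meta$trainLoss
  expect_lt(loss[length(loss)], loss[1])
  # non-increasing trend on a 10-epoch moving average
  ma <- stats::filter(loss, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
})

test_that("early stopping restores the best validation-loss weights", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5)
  y <- cbind(X %*% rnorm(5))
  val <- list(X = matrix(rnorm(50), 10, 5))
  val$Y <- cbind(val$X %*% rnorm(5))  # mismatched target: val loss plateaus
  f <- drtransfer:::trainDenseNet(X, y, hidden = c(8), lr = 1e-2,
                                  batchSize = 10, epochs = 500, patience = 30,
                                  val = val, seed = 4L)
  expect_lt(f$meta$epochsRun, 500)
  expect_equal(f$meta$epochsRun, f$meta$bestEpoch + 30)
  vl <- f$meta$valLoss
  # returned weights correspond to the best epoch, not the last one
  pred <- drtransfer:::predictDenseNet(f, val$X)
  expect_equal(mean((pred - val$Y)^2), min(vl), tolerance = 1e-8)
})

test_that("KL-trained softmax network approaches a fixed target simplex", {
  set.seed(4)
  X <- matrix(rnorm(240), 60, 4)
  target <- c(0.55, 0.25, 0.15, 0.05)
  Y <- matrix(target, 60, 4, byrow = TRUE)
  f <- drtransfer:::trainDenseNet(X, Y, hidden = c(16), outputType = "softmax",
                                  lr = 5e-3, batchSize = 20, epochs = 200,
                                  seed = 5L)
  pred <- drtransfer:::predictDenseNet(f, X)
  tv <- 0.5 * rowSums(abs(sweep(pred, 2, target)))
  expect_lt(mean(tv), 0.05)
})
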