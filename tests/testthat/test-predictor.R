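test_that("ensemble prediction is the arithmetic mean of member outputs", {
  nz <- sharedNormalized()
  model <- sharedModel()
  perMember <- predictResponse(model, nz$target, perMember = TRUE)
  expect_equal(predictResponse(model, nz$target), rowMeans(perMember),
               tolerance = 1e-12)
  # constant-output members: hidden node dead (ReLU(0)), bias carries c
  p <- length(geneIds(nz$source))
  constNet <- function(c0) drtransfer:::newDenseNet(
    list(matrix(0, p, 1), matrix(0, 1, 1)), list(0, c0), "linear")
  twoConst <- methods::new("TrainedPredictor",
                           members = list(constNet(1), constNet(3)),
                           hidden = 1L, dropout = 0,
                           hyperparams = list(lr = 0, batchSize = 1L,
                                              epochs = 0L),
                           geneIds = geneIds(nz$source),
                           labelNormalizer = NULL, baseSeed = 0L)
  expect_equal(unname(predictResponse(twoConst, nz$target)),
               rep(2, length(sampleIds(nz$target))))
  # K = 1: ensemble equals the single member
  one <- methods::new("TrainedPredictor", members = model@members[1],
                      hidden = model@hidden, dropout = model@dropout,
                      hyperparams = model@hyperparams,
                      geneIds = model@geneIds, labelNormalizer = NULL,
                      baseSeed = model@baseSeed)
  expect_equal(predictResponse(one, nz$target), perMember[, 1],
               tolerance = 1e-12)
})

test_that("inference is deterministic and row-equivariant", {
  nz <- sharedNormalized()
  model <- sharedModel()
  X <- exprValues(nz$target)
  expect_identical(predictResponse(model, X), predictResponse(model, X))
  perm <- rev(seq_len(nrow(X)))
  expect_equal(unname(predictResponse(model, X[perm, ])),
               unname(predictResponse(model, X)[perm]), tolerance = 1e-12)
  # column order is reconciled by gene name, mismatched sets rejected
  expect_equal(predictResponse(model, X[, rev(colnames(X))]),
               predictResponse(model, X), tolerance = 1e-12)
  expect_error(predictResponse(model, X[, -1]), "gene sets differ")
})

test_that("latent embedding is the last hidden layer", {
  nz <- sharedNormalized()
  model <- sharedModel()
  X <- exprValues(nz$target)
  emb <- embedSamples(model, X, member = 1)
  expect_identical(dim(emb), c(nrow(X), 8L))   # last hidden width
  # identical samples give identical embedding rows
  Xdup <- rbind(X[1, , drop = FALSE], X[1, , drop = FALSE])
  rownames(Xdup) <- c("a", "b")
  ed <- embedSamples(model, Xdup, member = 1)
  expect_equal(unname(ed[1, ]), unname(ed[2, ]), tolerance = 1e-15)
  # zero weights map any input to a zero embedding
  p <- ncol(X)
  zero <- handPredictor(list(matrix(0, p, 4), matrix(0, 4, 1)),
                        list(rep(0, 4), 0), colnames(X))
  expect_true(all(embedSamples(zero, X, member = 1) == 0))
  expect_error(embedSamples(model, X, member = 99), "out of range")
  # averaged embedding equals the member mean
  each <- embedSamples(model, X, member = "each")
  expect_equal(embedSamples(model, X, member = "all"),
               Reduce(`+`, each) / length(each), tolerance = 1e-12)
})

test_that("ensemble training is reproducible from the base seed", {
  nz <- sharedNormalized()
  hp <- list(lr = 1e-3, batchSize = 16L, epochs = 15L)
  m1 <- trainEnsemble(nz$source, nz$y, hp, K = 2, baseSeed = 5,
                      hidden = c(16L, 8L))
  m2 <- trainEnsemble(nz$source, nz$y, hp, K = 2, baseSeed = 5,
                      hidden = c(16L, 8L))
  expect_equal(predictResponse(m1, nz$target), predictResponse(m2, nz$target),
               tolerance = 1e-12)
})

test_that("grid search picks a converging learning rate over a diverging one", {
  set.seed(11)
  X <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(paste0("s", 1:60), paste0("g", 1:8)))
  y <- drop(X %*% rnorm(8)) + rnorm(60, 0, 0.1)
  y <- normalizeLabels(y)$values
  grid <- data.frame(lr = c(1e-3, 1e3), batchSize = c(16L, 16L))
  tuned <- tuneHyperparameters(X, y, grid = grid, folds = 3,
                               hidden = c(16L, 8L), maxEpochs = 60,
                               patience = 10, seed = 2)
  expect_equal(tuned$lr, 1e-3)
  expect_gte(tuned$epochs, 1)
  # singleton grid: that configuration is returned with its median epoch
  single <- tuneHyperparameters(X, y, grid = data.frame(lr = 1e-3,
                                                        batchSize = 16L),
                                folds = 3, hidden = c(16L, 8L),
                                maxEpochs = 30, patience = 10, seed = 2)
  expect_equal(single$lr, 1e-3)
  expect_equal(single$batchSize, 16L)
  # determinism: same seed, same fold assignment, same selection
  again <- tuneHyperparameters(X, y, grid = grid, folds = 3,
                               hidden = c(16L, 8L), maxEpochs = 60,
                               patience = 10, seed = 2)
  expect_identical(tuned$cvTable$meanPearson, again$cvTable$meanPearson)
})

test_that("a trained model round-trips through the text model directory", {
  nz <- sharedNormalized()
  model <- sharedModel()
  dir <- file.path(tempdir(), "modeldir")
  writePredictor(model, dir)
  back <- readPredictor(dir)
  expect_identical(back@geneIds, model@geneIds)
  expect_identical(back@labelNormalizer@drug, "fixture-drug")
  expect_equal(predictResponse(back, nz$target),
               predictResponse(model, nz$target), tolerance = 1e-6)
})

test_that("member predictions vary but averaging does not hurt worst member", {
  nz <- sharedNormalized()
  model <- sharedModel()
  d <- nz$data
  perMember <- predictResponse(model, nz$target, perMember = TRUE)
  sds <- apply(perMember, 1, sd)
  expect_true(all(is.finite(sds)))
  expect_gt(mean(sds), 0)
  # held-out MSE of the mean <= worst member (oracle continuous response)
  yT <- normalizeLabels(unname(d@targetResponse))$values
  mseMean <- mean((rowMeans(perMember) - yT)^2)
  msePer <- apply(perMember, 2, function(p) mean((p - yT)^2))
  expect_lte(mseMean, max(msePer) + 1e-12)
})
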