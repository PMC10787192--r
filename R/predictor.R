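# Phase 1: the dense-network ln IC50 regressor — hyperparameter tuning by
# 5-fold cross-validation, final full-data retraining, and a 10-seed mean
# ensemble.

asModelMatrix <- function(x, geneOrder = NULL) {
  m <- if (methods::is(x, "GeneExpression")) exprValues(x) else as.matrix(x)
  if (!is.null(geneOrder)) {
    if (!identical(colnames(m), geneOrder)) {
      if (!setequal(colnames(m), geneOrder))
        stop("gene sets differ from the model's gene order; missing: ",
             paste(head(setdiff(geneOrder, colnames(m)), 5), collapse = ", "))
      m <- m[, geneOrder, drop = FALSE]
    }
  }
  m
}

#' Default hyperparameter grid
#'
#' The grid searched when none is supplied: learning rates `1e-3` and
#' `1e-4`, batch sizes 32 and 128. The maximum epoch count (1000, early
#' stopping at patience 30) is fixed rather than searched.
#'
#' @return data.frame with columns `lr` and `batchSize`.
#' @export
defaultGrid <- function() {
  expand.grid(lr = c(1e-3, 1e-4), batchSize = c(32L, 128L),
              KEEP.OUT.ATTRS = FALSE)
}

#' Tune predictor hyperparameters by cross-validated Pearson correlation
#'
#' Grid search with k-fold cross-validation on the labeled source cohort.
#' For every grid point each fold trains with early stopping monitored on
#' the held-out fold (up to `maxEpochs`, patience `patience`); the grid
#' point with the highest mean Pearson correlation between predictions and
#' labels over the validation folds wins. Because the final full-data
#' retraining has no validation set, the epoch count it should use is taken
#' as the median best epoch across the winning grid point's folds.
#'
#' @param x source cohort ([GeneExpression-class] or samples-by-genes
#'   matrix), normalized.
#' @param y normalized labels, one per sample.
#' @param grid data.frame of candidate `lr`/`batchSize` pairs.
#' @param folds number of cross-validation folds.
#' @param hidden hidden-layer widths.
#' @param dropout dropout probability before the output layer.
#' @param maxEpochs cap on training epochs during tuning.
#' @param patience early-stopping patience in epochs.
#' @param seed seed for fold assignment and member initialization.
#' @return list: `lr`, `batchSize`, `epochs` (median early-stop epoch),
#'   `cvTable` (per grid point mean fold correlation).
#' @export
tuneHyperparameters <- function(x, y, grid = defaultGrid(), folds = 5L,
                                hidden = c(512L, 256L, 128L), dropout = 0.2,
                                maxEpochs = 1000L, patience = 30L,
                                seed = 1L) {
  X <- asModelMatrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < folds) stop("fewer samples than folds")
  if (!nrow(grid)) stop("empty hyperparameter grid")
  if (any(grid$lr <= 0) || any(grid$batchSize < 1))
    stop("grid entries must be positive")

  set.seed(seed)
  foldId <- sample(rep_len(seq_len(folds), n))

  meanR <- numeric(nrow(grid))
  medEpoch <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rs <- numeric(folds)
    eps <- integer(folds)
    for (f in seq_len(folds)) {
      tr <- foldId != f
      fit <- trainDenseNet(X[tr, , drop = FALSE],
                           cbind(y[tr]), hidden = hidden,
                           outputType = "linear", dropout = dropout,
                           lr = grid$lr[g], batchSize = grid$batchSize[g],
                           epochs = maxEpochs, patience = patience,
                           val = list(X = X[!tr, , drop = FALSE],
                                      Y = cbind(y[!tr])),
                           seed = seed + 1000L * g + f)
      pred <- predictDenseNet(fit, X[!tr, , drop = FALSE])[, 1]
      rs[f] <- if (sd(pred) == 0 || sd(y[!tr]) == 0) NA_real_
               else cor(pred, y[!tr])
      eps[f] <- fit$meta$bestEpoch
    }
    meanR[g] <- mean(rs, na.rm = TRUE)
    medEpoch[g] <- as.integer(round(median(eps)))
  }
  if (all(is.nan(meanR) | is.na(meanR)))
    stop("all grid points produced undefined validation correlations")
  best <- which.max(meanR)
  list(lr = grid$lr[best], batchSize = as.integer(grid$batchSize[best]),
       epochs = max(1L, medEpoch[best]),
       cvTable = cbind(grid, meanPearson = meanR, medianEpoch = medEpoch))
}

#' Train the seed-ensemble regressor
#'
#' Trains `K` members with identical architecture on all labeled source
#' samples (no validation holdout), member `k` seeded with
#' `baseSeed + k - 1`, MSE loss, and the tuned epoch count. The ensemble
#' prediction is the arithmetic mean of member outputs.
#'
#' @param x normalized source cohort ([GeneExpression-class] or matrix).
#' @param y normalized labels.
#' @param hyperparams list with `lr`, `batchSize`, `epochs` (e.g. from
#'   [tuneHyperparameters()]).
#' @param K ensemble size.
#' @param baseSeed base random seed.
#' @param hidden hidden-layer widths; the last width is the latent-embedding
#'   dimension.
#' @param dropout dropout probability before the output layer.
#' @param labelNormalizer optional [LabelNormalizer-class] stored for
#'   back-transformation.
#' @return a [TrainedPredictor-class].
#' @export
trainEnsemble <- function(x, y, hyperparams, K = 10L, baseSeed = 1L,
                          hidden = c(512L, 256L, 128L), dropout = 0.2,
                          labelNormalizer = NULL) {
  X <- asModelMatrix(x)
  y <- as.numeric(y)
  stopifnot(K >= 1, nrow(X) == length(y))
  members <- vector("list", K)
  for (k in seq_len(K)) {
    members[[k]] <- trainDenseNet(
      X, cbind(y), hidden = hidden, outputType = "linear",
      dropout = dropout, lr = hyperparams$lr,
      batchSize = hyperparams$batchSize, epochs = hyperparams$epochs,
      patience = 0L, seed = baseSeed + k - 1L)
  }
  methods::new("TrainedPredictor", members = members,
               hidden = as.integer(hidden), dropout = dropout,
               hyperparams = hyperparams[c("lr", "batchSize", "epochs")],
               geneIds = colnames(X),
               labelNormalizer = labelNormalizer,
               baseSeed = as.integer(baseSeed))
}

#' Predict normalized drug response
#'
#' Ensemble-mean prediction on the normalized ln IC50 scale. Dropout is
#' disabled at inference; output is deterministic given fixed weights.
#'
#' @param model a [TrainedPredictor-class].
#' @param x normalized cohort ([GeneExpression-class] or matrix) whose gene
#'   set matches the model's gene order.
#' @param perMember return the samples-by-members matrix of member
#'   predictions instead of their mean.
#' @return named numeric vector of predictions (or a matrix when
#'   `perMember = TRUE`).
#' @export
predictResponse <- function(model, x, perMember = FALSE) {
  stopifnot(methods::is(model, "TrainedPredictor"))
  X <- asModelMatrix(x, geneOrder = model@geneIds)
  preds <- vapply(model@members,
                  function(m) predictDenseNet(m, X)[, 1],
                  numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1)
  rownames(preds) <- rownames(X)
  if (perMember) return(preds)
  rowMeans(preds)
}

#' Extract latent embeddings from the encoder
#'
#' Activations of the last hidden layer (post-ReLU, pre-dropout) — the
#' representation the output layer consumes — for one member or averaged
#' over all members.
#'
#' @param model a [TrainedPredictor-class].
#' @param x normalized cohort ([GeneExpression-class] or matrix).
#' @param member member index, or `"all"` to average member embeddings, or
#'   `"each"` for a list of per-member matrices.
#' @return samples-by-d matrix (d = last hidden width), or a list of them.
#' @export
embedSamples <- function(model, x, member = "all") {
  stopifnot(methods::is(model, "TrainedPredictor"))
  X <- asModelMatrix(x, geneOrder = model@geneIds)
  if (identical(member, "each"))
    return(lapply(model@members, function(m) hiddenDenseNet(m, X)))
  if (identical(member, "all")) {
    embs <- lapply(model@members, function(m) hiddenDenseNet(m, X))
    return(Reduce(`+`, embs) / length(embs))
  }
  member <- as.integer(member)
  if (member < 1 || member > length(model@members))
    stop("member index out of range")
  hiddenDenseNet(model@members[[member]], X)
}

#' Save / load a trained predictor as a text model directory
#'
#' The model is written as one CSV weight file per layer per member plus a
#' JSON manifest (architecture, hyperparameters, seeds, gene order, label
#' normalizer).
#'
#' @param model a [TrainedPredictor-class].
#' @param dir directory to create.
#' @return `dir` invisibly; `readPredictor` returns the restored model.
#' @export
writePredictor <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(hidden = model@hidden, dropout = model@dropout,
                   hyperparams = model@hyperparams,
                   geneIds = model@geneIds, baseSeed = model@baseSeed,
                   K = length(model@members))
  if (!is.null(model@labelNormalizer))
    manifest$labelNormalizer <- list(drug = model@labelNormalizer@drug,
                                     mu = model@labelNormalizer@mu,
                                     sigma = model@labelNormalizer@sigma)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(model@members)) {
    net <- model@members[[k]]
    for (l in seq_along(net$weights)) {
      write.table(net$weights[[l]],
                  file.path(dir, sprintf("member%02d_W%d.csv", k, l)),
                  sep = ",", row.names = FALSE, col.names = FALSE)
      write.table(cbind(net$biases[[l]]),
                  file.path(dir, sprintf("member%02d_b%d.csv", k, l)),
                  sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname writePredictor
#' @export
readPredictor <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  nLayers <- length(manifest$hidden) + 1L
  members <- lapply(seq_len(manifest$K), function(k) {
    W <- lapply(seq_len(nLayers), function(l)
      as.matrix(read.csv(file.path(dir, sprintf("member%02d_W%d.csv", k, l)),
                         header = FALSE)))
    b <- lapply(seq_len(nLayers), function(l)
      read.csv(file.path(dir, sprintf("member%02d_b%d.csv", k, l)),
               header = FALSE)[[1]])
    W <- lapply(W, function(m) {dimnames(m) <- NULL; m})
    newDenseNet(W, b, "linear")
  })
  ln <- NULL
  if (!is.null(manifest$labelNormalizer))
    ln <- methods::new("LabelNormalizer",
                       drug = manifest$labelNormalizer$drug,
                       mu = manifest$labelNormalizer$mu,
                       sigma = manifest$labelNormalizer$sigma)
  methods::new("TrainedPredictor", members = members,
               hidden = as.integer(manifest$hidden),
               dropout = manifest$dropout,
               hyperparams = as.list(manifest$hyperparams),
               geneIds = as.character(manifest$geneIds),
               labelNormalizer = ln,
               baseSeed = as.integer(manifest$baseSeed))
}
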