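# Thin R wrappers over the compiled dense-network core. A fitted network is
# a plain list (weights, biases, history) of class "denseNet"; the S4
# ensemble classes hold lists of these.

newDenseNet <- function(weights, biases, outputType, meta = list()) {
  structure(list(weights = weights, biases = biases,
                 outputType = outputType, meta = meta),
            class = "denseNet")
}

#' @export
print.denseNet <- function(x, ...) {
  dims <- vapply(x$weights, nrow, integer(1))
  cat(sprintf("denseNet: %s -> %d output (%s)\n",
              paste(c(dims, ncol(x$weights[[length(x$weights)]])),
                    collapse = " -> "),
              ncol(x$weights[[length(x$weights)]]), x$outputType))
  invisible(x)
}

# Train one network. outputType "linear" pairs with MSE loss, "softmax" with
# KL(target || prediction). Early stopping (patience > 0) monitors the
# validation loss when val is supplied, otherwise the training loss, and
# restores the best weights.
trainDenseNet <- function(X, Y, hidden, outputType = c("linear", "softmax"),
                          dropout = 0, lr = 1e-3, batchSize = 32,
                          epochs = 100, patience = 0, val = NULL,
                          seed = 1L) {
  outputType <- match.arg(outputType)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  sizes <- as.integer(c(ncol(X), hidden, ncol(Y)))
  init <- .nn_init(sizes, as.integer(seed))
  Xv <- if (is.null(val)) NULL else as.matrix(val$X)
  Yv <- if (is.null(val)) NULL else as.matrix(val$Y)
  fit <- .nn_train(X, Y, init$weights, init$biases,
                   ifelse(outputType == "softmax", 1L, 0L),
                   dropout, lr, as.integer(batchSize), as.integer(epochs),
                   as.integer(patience), Xv, Yv, as.integer(seed))
  newDenseNet(fit$weights, fit$biases, outputType,
              meta = list(hidden = as.integer(hidden), dropout = dropout,
                          lr = lr, batchSize = batchSize,
                          epochs = epochs, seed = seed,
                          trainLoss = fit$train_loss,
                          valLoss = fit$val_loss,
                          bestEpoch = fit$best_epoch,
                          epochsRun = fit$epochs_run,
                          bestLoss = fit$best_loss))
}

predictDenseNet <- function(net, X) {
  out <- .nn_forward(net$weights, net$biases, as.matrix(X),
                     ifelse(net$outputType == "softmax", 1L, 0L))
  rownames(out) <- rownames(X)
  out
}

hiddenDenseNet <- function(net, X) {
  out <- .nn_hidden(net$weights, net$biases, as.matrix(X))
  rownames(out) <- rownames(X)
  out
}
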