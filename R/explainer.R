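# Phase 2: masking-based Granger contribution targets, explainer-network
# distillation via KL divergence, median-ensemble scoring, and per-drug
# aggregation.

predictAny <- function(model, X) {
  if (is.function(model)) as.numeric(model(X)) else predictResponse(model, X)
}

#' Masking-based Granger contribution targets
#'
#' For each sample X with true (normalized) label y, the predictor's
#' baseline squared error is `eps = (y - yhat)^2` with `yhat` the ensemble
#' mean. Zeroing out gene i (in the normalized space, i.e. setting it to the
#' reference-pool mean) gives the masked error `eps_i`; the gene's
#' contribution is the normalized error increase
#' `omega_i = max(eps_i - eps, 0) / sum_j max(eps_j - eps, 0)`. Negative
#' increases are clamped to zero so each vector lies on the probability
#' simplex; when every delta is zero the uniform vector `1/p` is returned
#' and the sample flagged.
#'
#' @param model a [TrainedPredictor-class], or any function mapping a
#'   samples-by-genes matrix to a numeric prediction vector.
#' @param x normalized samples-by-genes matrix or
#'   [GeneExpression-class].
#' @param y normalized labels, one per sample.
#' @param clampNegative clamp negative error increases to zero (default);
#'   `FALSE` shifts each vector by its minimum instead.
#' @return a [ContributionSet-class] with `type = "target"`.
#' @export
grangerContributions <- function(model, x, y, clampNegative = TRUE) {
  X <- if (methods::is(x, "GeneExpression")) exprValues(x) else as.matrix(x)
  if (methods::is(model, "TrainedPredictor"))
    X <- asModelMatrix(X, geneOrder = model@geneIds)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, p >= 1)
  yhat <- predictAny(model, X)
  if (!all(is.finite(yhat))) stop("non-finite baseline prediction")
  eps <- (y - yhat)^2
  delta <- matrix(0, n, p)
  for (i in seq_len(p)) {
    Xi <- X
    Xi[, i] <- 0
    yi <- predictAny(model, Xi)
    if (!all(is.finite(yi))) stop("non-finite masked prediction for gene ", i)
    delta[, i] <- (y - yi)^2 - eps
  }
  if (clampNegative) {
    delta[delta < 0] <- 0
  } else {
    delta <- delta - pmin(apply(delta, 1, min), 0)
  }
  tot <- rowSums(delta)
  uniform <- tot == 0
  omega <- delta / ifelse(tot == 0, 1, tot)
  if (any(uniform)) {
    omega[uniform, ] <- 1 / p
    message(sum(uniform), " sample(s) had no error increase under any mask; ",
            "uniform contributions substituted")
  }
  sampleIds <- rownames(X)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(n))
  gid <- colnames(X)
  if (is.null(gid)) gid <- paste0("gene", seq_len(p))
  dimnames(omega) <- list(sampleIds, gid)
  methods::new("ContributionSet", omega = omega, eps = unname(eps),
               geneIds = gid, sampleIds = sampleIds, type = "target",
               uniformFallback = uniform)
}

#' Distill contribution targets into an explainer ensemble
#'
#' Trains `nExplainers` independent feed-forward networks, each mapping a
#' normalized expression vector to a simplex contribution vector through
#' ReLU hidden layers and a softmax output, by minimizing the KL divergence
#' `KL(target || prediction)` over the training samples. Targets default to
#' the masking-based contributions of the training cohort but may be
#' supplied precomputed.
#'
#' @param model the trained [TrainedPredictor-class] being explained.
#' @param x normalized training cohort (matrix or
#'   [GeneExpression-class]).
#' @param y normalized training labels.
#' @param nExplainers ensemble size.
#' @param hidden hidden units per layer.
#' @param layers number of hidden layers.
#' @param epochs,lr,batchSize explainer training settings.
#' @param baseSeed explainer k uses `baseSeed + k - 1`.
#' @param targets optional precomputed [ContributionSet-class] (or
#'   samples-by-genes simplex matrix) overriding the masking computation.
#' @return an [ExplainerEnsemble-class].
#' @export
trainExplainer <- function(model, x, y, nExplainers = 10L, hidden = 512L,
                           layers = 2L, epochs = 150L, lr = 1e-3,
                           batchSize = 32L, baseSeed = 101L,
                           targets = NULL) {
  X <- if (methods::is(x, "GeneExpression")) exprValues(x) else as.matrix(x)
  if (methods::is(model, "TrainedPredictor"))
    X <- asModelMatrix(X, geneOrder = model@geneIds)
  if (is.null(targets)) targets <- grangerContributions(model, X, y)
  Om <- if (methods::is(targets, "ContributionSet")) targets@omega
        else as.matrix(targets)
  stopifnot(nrow(Om) == nrow(X), ncol(Om) == ncol(X))
  if (all(abs(Om - 1 / ncol(Om)) < 1e-12))
    warning("all contribution targets are uniform; explainer will learn ",
            "nothing informative")
  members <- vector("list", nExplainers)
  for (k in seq_len(nExplainers)) {
    members[[k]] <- trainDenseNet(X, Om, hidden = rep(hidden, layers),
                                  outputType = "softmax", dropout = 0,
                                  lr = lr, batchSize = batchSize,
                                  epochs = epochs, patience = 0L,
                                  seed = baseSeed + k - 1L)
  }
  gid <- colnames(X)
  if (is.null(gid)) gid <- paste0("gene", seq_len(ncol(X)))
  methods::new("ExplainerEnsemble", members = members, geneIds = gid,
               hidden = as.integer(hidden), nLayers = as.integer(layers))
}

#' Predict contribution vectors for new samples
#'
#' One forward pass per explainer; per-gene scores are the elementwise
#' median across explainers, re-normalized so every sample's vector sums to
#' one.
#'
#' @param explainers an [ExplainerEnsemble-class].
#' @param x normalized cohort (matrix or [GeneExpression-class]),
#'   typically the tissue-informed-normalized test samples.
#' @return a [ContributionSet-class] with `type = "predicted"`.
#' @export
scoreSamples <- function(explainers, x) {
  stopifnot(methods::is(explainers, "ExplainerEnsemble"))
  X <- if (methods::is(x, "GeneExpression")) exprValues(x) else as.matrix(x)
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), explainers@geneIds))
      stop("gene sets differ from the explainer's gene order; missing: ",
           paste(head(setdiff(explainers@geneIds, colnames(X)), 5),
                 collapse = ", "))
    X <- X[, explainers@geneIds, drop = FALSE]
  }
  preds <- lapply(explainers@members, function(m) predictDenseNet(m, X))
  arr <- array(unlist(preds), dim = c(nrow(X), ncol(X), length(preds)))
  med <- apply(arr, c(1, 2), median)
  med <- med / rowSums(med)
  sampleIds <- rownames(X)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(X)))
  dimnames(med) <- list(sampleIds, explainers@geneIds)
  methods::new("ContributionSet", omega = med, eps = numeric(),
               geneIds = explainers@geneIds, sampleIds = sampleIds,
               type = "predicted",
               uniformFallback = logical(nrow(X)))
}

#' Aggregate contribution scores into per-drug gene scores
#'
#' Averages each gene's predicted contribution over the labeled test
#' samples and rescales so the largest aggregated score equals 1.
#'
#' @param scores a [ContributionSet-class].
#' @param labeledSampleIds samples to average over; defaults to all samples
#'   in `scores`.
#' @param drug drug name recorded on the result.
#' @return a [DrugGeneScores-class].
#' @export
aggregateScores <- function(scores, labeledSampleIds = NULL, drug = "drug") {
  stopifnot(methods::is(scores, "ContributionSet"))
  if (is.null(labeledSampleIds)) labeledSampleIds <- scores@sampleIds
  idx <- match(labeledSampleIds, scores@sampleIds)
  if (anyNA(idx))
    stop("sample(s) absent from the contribution set: ",
         paste(head(labeledSampleIds[is.na(idx)], 5), collapse = ", "))
  if (!length(idx)) stop("empty sample set")
  bar <- colMeans(scores@omega[idx, , drop = FALSE])
  bar <- bar / max(bar)
  methods::new("DrugGeneScores", geneIds = scores@geneIds,
               score = unname(bar), drug = drug,
               nSamples = length(idx))
}

#' Write aggregated gene scores as a ranked table
#'
#' @param scores a [DrugGeneScores-class].
#' @param path output TSV path (columns gene, score, rank).
#' @return `path`, invisibly.
#' @export
writeGeneScores <- function(scores, path) {
  ord <- order(scores@score, decreasing = TRUE)
  df <- data.frame(gene = scores@geneIds[ord], score = scores@score[ord],
                   rank = seq_along(ord))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
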