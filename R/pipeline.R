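# End-to-end orchestration: one run = one drug, every source of randomness
# funneled through one base seed recorded in the manifest.

#' Pipeline configuration
#'
#' Collects every tunable of a single-drug run. With `tune = TRUE` the
#' hyperparameter grid is searched by cross-validation; otherwise the first
#' grid row and `epochs` are used as-is.
#'
#' @param drug drug name.
#' @param mode normalization mode for the target cohort:
#'   `"tissue_informed"` (z-score against the tissue-restricted unlabeled
#'   pool), `"train_norm"` (source statistics applied to both cohorts) or
#'   `"test_norm"` (target fitted on itself).
#' @param hidden predictor hidden-layer widths.
#' @param dropout dropout probability before the predictor output.
#' @param K predictor ensemble size.
#' @param nExplainers explainer ensemble size.
#' @param grid data.frame of `lr`/`batchSize` candidates.
#' @param tune run the cross-validated grid search.
#' @param epochs final-training epochs when not tuning.
#' @param maxEpochs,patience,folds tuning settings.
#' @param explainerHidden,explainerLayers,explainerEpochs explainer
#'   settings.
#' @param percentiles percentile grid for the precision table.
#' @param baseSeed base random seed for the whole run.
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(drug = "drug",
                           mode = c("tissue_informed", "train_norm",
                                    "test_norm"),
                           hidden = c(512L, 256L, 128L), dropout = 0.2,
                           K = 10L, nExplainers = 10L,
                           grid = defaultGrid(), tune = FALSE,
                           epochs = 100L, maxEpochs = 1000L,
                           patience = 30L, folds = 5L,
                           explainerHidden = 512L, explainerLayers = 2L,
                           explainerEpochs = 150L,
                           percentiles = seq(5, 50, by = 5),
                           baseSeed = 1L) {
  mode <- match.arg(mode)
  stopifnot(K >= 1, nExplainers >= 1, epochs >= 1, maxEpochs >= 1,
            all(grid$lr > 0), all(grid$batchSize >= 1),
            all(percentiles > 0), all(percentiles <= 50))
  structure(list(drug = drug, mode = mode, hidden = as.integer(hidden),
                 dropout = dropout, K = as.integer(K),
                 nExplainers = as.integer(nExplainers), grid = grid,
                 tune = tune, epochs = as.integer(epochs),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), folds = as.integer(folds),
                 explainerHidden = as.integer(explainerHidden),
                 explainerLayers = as.integer(explainerLayers),
                 explainerEpochs = as.integer(explainerEpochs),
                 percentiles = percentiles,
                 baseSeed = as.integer(baseSeed)),
            class = "pipelineConfig")
}

# Normalize the source and target cohorts under the configured mode. The
# source cohort is always z-scored on itself; the modes differ only in the
# statistics applied to the target samples.
normalizeCohorts <- function(config, source, target, pool) {
  sourceStats <- fitZscore(source, mode = "train_norm")
  targetStats <- switch(
    config$mode,
    tissue_informed = {
      ti <- tissueOf(target)
      if (is.null(ti)) stop("target cohort carries no tissue labels")
      fitTissueInformed(pool, targetTissues = unique(ti),
                        excludeSamples = sampleIds(target))
    },
    train_norm = sourceStats,
    test_norm = fitZscore(target, mode = "test_norm"))
  list(source = applyNormalizer(source, sourceStats),
       target = applyNormalizer(target, targetStats),
       sourceStats = sourceStats, targetStats = targetStats)
}

#' Run the full two-phase pipeline for one drug
#'
#' Phase 1: preprocess (expression filter on a raw target cohort, gene
#' intersection), normalize under the configured mode, optionally tune by
#' cross-validation, train the seed ensemble on the labeled source cohort,
#' and predict the target samples. Phase 2: compute masking-based
#' contribution targets on the training cohort, distill them into the
#' explainer ensemble, score the target samples, aggregate per-drug gene
#' scores, and cut the panel at the knee. Evaluation statistics are
#' computed when target labels are supplied.
#'
#' @param config a [pipelineConfig()] list.
#' @param source labeled source [GeneExpression-class].
#' @param sourceResponse named numeric ln IC50 labels for the source
#'   samples.
#' @param target [GeneExpression-class] of evaluation samples.
#' @param targetLabels optional named `"sensitive"`/`"resistant"` labels.
#' @param pool unlabeled target-domain [GeneExpression-class] used by the
#'   tissue-informed normalizer.
#' @param outDir optional directory; when given, predictions, scores, the
#'   panel, the evaluation report and the manifest are written there.
#' @return list: `predictions` (named, normalized scale), `model`,
#'   `explainers`, `contributions`, `geneScores`
#'   ([DrugGeneScores-class]), `knee` ([KneeResult-class]), `eval`
#'   (or NULL), `normalizers`, `manifest`.
#' @export
runPipeline <- function(config, source, sourceResponse, target,
                        targetLabels = NULL, pool = NULL, outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    out <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }
  stage <- function(name, expr) {
    tryCatch(tick(name, expr),
             error = function(e) stop("pipeline stage '", name,
                                      "' failed: ", conditionMessage(e),
                                      call. = FALSE))
  }

  if (!"log2" %in% transformsOf(target))
    target <- stage("filter_target", filterTargetGenes(target))
  both <- stage("intersect", intersectGenes(source, target))
  source <- both$source
  target <- both$target
  if (config$mode == "tissue_informed") {
    if (is.null(pool)) stop("tissue_informed mode requires a pool")
    pool <- pool[geneIds(source), ]
  }

  nz <- stage("normalize", normalizeCohorts(config, source, target, pool))
  y <- sourceResponse[sampleIds(source)]
  if (anyNA(y)) stop("source samples without a response label")
  ln <- normalizeLabels(unname(y), drug = config$drug)

  hp <- if (config$tune) {
    stage("tune", tuneHyperparameters(
      nz$source, ln$values, grid = config$grid, folds = config$folds,
      hidden = config$hidden, dropout = config$dropout,
      maxEpochs = config$maxEpochs, patience = config$patience,
      seed = config$baseSeed))
  } else {
    list(lr = config$grid$lr[1],
         batchSize = as.integer(config$grid$batchSize[1]),
         epochs = config$epochs)
  }

  model <- stage("train", trainEnsemble(
    nz$source, ln$values, hyperparams = hp, K = config$K,
    baseSeed = config$baseSeed, hidden = config$hidden,
    dropout = config$dropout, labelNormalizer = ln$normalizer))

  predictions <- stage("predict", predictResponse(model, nz$target))

  evalReport <- NULL
  if (!is.null(targetLabels)) {
    labs <- as.character(targetLabels[names(predictions)])
    if (anyNA(labs)) stop("target samples without a label")
    evalReport <- stage("evaluate", evaluateTransfer(
      predictions, labs, percentiles = config$percentiles,
      drug = config$drug))
  }

  explainers <- stage("explain_train", trainExplainer(
    model, nz$source, ln$values, nExplainers = config$nExplainers,
    hidden = config$explainerHidden, layers = config$explainerLayers,
    epochs = config$explainerEpochs, baseSeed = config$baseSeed + 100L))
  contributions <- stage("explain_score", scoreSamples(explainers,
                                                       nz$target))
  labeledIds <- if (is.null(targetLabels)) NULL
                else intersect(sampleIds(target), names(targetLabels))
  geneScores <- stage("aggregate", aggregateScores(
    contributions, labeledSampleIds = labeledIds, drug = config$drug))
  knee <- stage("knee", selectPanel(geneScores))

  manifest <- list(config = config[setdiff(names(config), "grid")],
                   grid = as.list(config$grid),
                   hyperparams = hp[c("lr", "batchSize", "epochs")],
                   nSource = length(sampleIds(source)),
                   nTarget = length(sampleIds(target)),
                   nGenes = length(geneIds(source)),
                   baseSeed = config$baseSeed,
                   timings = timings,
                   totalSeconds = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")),
                   rVersion = as.character(getRversion()))

  result <- list(predictions = predictions, model = model,
                 explainers = explainers, contributions = contributions,
                 geneScores = geneScores, knee = knee, eval = evalReport,
                 normalizers = nz[c("sourceStats", "targetStats")],
                 labelNormalizer = ln$normalizer, manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(sample_id = names(predictions),
                           prediction = unname(predictions)),
                file.path(outDir, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeGeneScores(geneScores, file.path(outDir, "gene_scores.tsv"))
    writeKneeResult(knee, file.path(outDir, "panel.tsv"))
    if (!is.null(evalReport)) {
      ev <- evalReport
      class(ev) <- NULL
      jsonlite::write_json(ev, file.path(outDir, "eval.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  result
}

#' Predict with inputs restricted to a gene panel
#'
#' Zeroes every gene outside the panel (in the normalized space, i.e. sets
#' it to the reference mean) before predicting — the small-panel predictive
#' power check.
#'
#' @param model a [TrainedPredictor-class].
#' @param x normalized cohort (matrix or [GeneExpression-class]).
#' @param panel character vector of panel genes, a subset of the model's
#'   gene order.
#' @return named numeric predictions.
#' @export
restrictToPanel <- function(model, x, panel) {
  stopifnot(methods::is(model, "TrainedPredictor"))
  panel <- as.character(panel)
  if (!length(panel)) stop("panel must be non-empty")
  bad <- setdiff(panel, model@geneIds)
  if (length(bad))
    stop("panel gene(s) unknown to the model: ",
         paste(head(bad, 5), collapse = ", "))
  X <- asModelMatrix(if (methods::is(x, "GeneExpression")) exprValues(x)
                     else as.matrix(x), geneOrder = model@geneIds)
  X[, !(colnames(X) %in% panel)] <- 0
  predictResponse(model, X)
}
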