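#' @import methods
#' @importFrom stats quantile sd rnorm runif cor pchisq wilcox.test median
#'   setNames
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib drtransfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Expression matrix container
#'
#' A [SummarizedExperiment::SummarizedExperiment]-backed container for a
#' cohort of expression profiles. Genes are stored in rows and samples in
#' columns (the Bioconductor convention); [exprValues()] returns the
#' transposed samples-by-genes matrix that the modeling code consumes.
#' Metadata records the domain (`"source"` for the cell-line-like cohort,
#' `"target"` for the tumor-like cohort), the expression units, and the list
#' of transforms already applied, which guards against applying a transform
#' twice.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]; the assay is
#'   named `"exprs"`, `colData` may carry a `tissue` column, and `metadata`
#'   holds `domain`, `units` and `transforms`.
#' @export
setClass("GeneExpression", contains = "SummarizedExperiment")

setValidity("GeneExpression", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is missing")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (anyNA(v)) msg <- c(msg, "expression values contain missing values")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample identifiers")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene identifiers")
  dom <- S4Vectors::metadata(object)$domain
  if (is.null(dom) || !dom %in% c("source", "target"))
    msg <- c(msg, "metadata$domain must be 'source' or 'target'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneExpression object
#'
#' @param values numeric matrix, samples in rows and genes in columns, with
#'   row and column names (sample and gene identifiers).
#' @param domain `"source"` or `"target"`.
#' @param tissue optional character vector of per-sample tissue labels.
#' @param units free-text expression units (e.g. `"raw-fpkm"`, `"log2"`,
#'   `"zscore"`).
#' @param transforms character vector of transforms already applied.
#' @return a [GeneExpression-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' ge <- geneExpression(m, domain = "source")
#' dim(exprValues(ge))
#' @export
geneExpression <- function(values, domain = c("source", "target"),
                           tissue = NULL, units = "unknown",
                           transforms = character()) {
  domain <- match.arg(domain)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample (row) and gene (column) names")
  if (anyNA(values)) {
    bad <- which(apply(values, 2, anyNA))
    stop("missing values in gene(s): ",
         paste(head(colnames(values)[bad], 5), collapse = ", "))
  }
  cd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(tissue)) {
    if (length(tissue) != nrow(values))
      stop("'tissue' must have one entry per sample")
    cd$tissue <- as.character(tissue)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(values)),
    colData = cd,
    metadata = list(domain = domain, units = units,
                    transforms = as.character(transforms)))
  methods::new("GeneExpression", se)
}

#' Per-gene normalization statistics
#'
#' Location/scale statistics fitted on a reference pool of samples, used to
#' z-score a matrix gene-wise. In `tissue_informed` mode the pool is the set
#' of unlabeled target-domain samples whose tissue belongs to the drug's
#' target tissues, with the evaluation samples excluded. Zero-variance genes
#' are flagged; when applied, their scale is treated as 1 so gene sets stay
#' aligned between cohorts.
#'
#' @slot geneIds character, gene identifiers in fit order.
#' @slot mu,sigma numeric per-gene location and (population) scale.
#' @slot flagged logical, TRUE for zero-variance genes.
#' @slot mode one of `"tissue_informed"`, `"train_norm"`, `"test_norm"`.
#' @slot referencePool list describing the samples the fit used.
#' @export
setClass("NormalizerStats",
         representation(geneIds = "character", mu = "numeric",
                        sigma = "numeric", flagged = "logical",
                        mode = "character", referencePool = "list"))

setValidity("NormalizerStats", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (length(object@mu) != n || length(object@sigma) != n ||
      length(object@flagged) != n)
    msg <- c(msg, "geneIds, mu, sigma and flagged lengths differ")
  if (any(object@sigma < 0)) msg <- c(msg, "negative sigma")
  if (!object@mode %in% c("tissue_informed", "train_norm", "test_norm"))
    msg <- c(msg, "unknown normalization mode")
  if (length(msg)) msg else TRUE
})

#' Drug-wise label normalizer
#'
#' Stores the mean and population standard deviation of a drug's ln IC50
#' labels so that predictions on the z-scored scale can be mapped back.
#'
#' @slot drug drug name.
#' @slot mu,sigma label moments; `sigma > 0`.
#' @export
setClass("LabelNormalizer",
         representation(drug = "character", mu = "numeric", sigma = "numeric"))

setValidity("LabelNormalizer", function(object) {
  if (object@sigma <= 0) "sigma must be > 0" else TRUE
})

#' Seed-ensemble of dense-network response regressors
#'
#' K independently trained feed-forward regressors sharing one architecture
#' (hidden ReLU layers, a dropout layer before the single linear output) and
#' one gene order; the ensemble prediction is the arithmetic mean of the
#' member outputs on the normalized ln IC50 scale.
#'
#' @slot members list of fitted networks (weights/biases per member).
#' @slot hidden integer hidden-layer widths.
#' @slot dropout dropout probability before the output layer.
#' @slot hyperparams list: `epochs`, `batchSize`, `lr`.
#' @slot geneIds input gene order.
#' @slot labelNormalizer a [LabelNormalizer-class] or NULL.
#' @slot baseSeed integer; member k uses seed `baseSeed + k - 1`.
#' @export
setClass("TrainedPredictor",
         representation(members = "list", hidden = "integer",
                        dropout = "numeric", hyperparams = "list",
                        geneIds = "character", labelNormalizer = "ANY",
                        baseSeed = "integer"))

setValidity("TrainedPredictor", function(object) {
  if (length(object@members) < 1) "ensemble needs at least one member"
  else TRUE
})

#' Explainer network ensemble
#'
#' Independently trained explainer networks distilled from masking-based
#' contribution targets; each maps a normalized expression vector to a
#' probability-simplex contribution vector. Final scores are the elementwise
#' median across members, re-normalized to sum to one.
#'
#' @slot members list of fitted softmax networks.
#' @slot geneIds gene order (input and output dimension p).
#' @slot hidden hidden width per layer.
#' @slot nLayers number of hidden layers.
#' @export
setClass("ExplainerEnsemble",
         representation(members = "list", geneIds = "character",
                        hidden = "integer", nLayers = "integer"))

#' Per-sample contribution vectors
#'
#' Holds one contribution vector per sample over p genes — either the
#' masking-based targets (each vector is the normalized increase in squared
#' prediction error when a gene is zeroed out) or the explainer-predicted
#' vectors. Every vector is nonnegative and sums to one.
#'
#' @slot omega numeric matrix, samples by genes, rows on the simplex.
#' @slot eps numeric per-sample baseline squared error (targets only).
#' @slot geneIds,sampleIds identifiers.
#' @slot type `"target"` or `"predicted"`.
#' @slot uniformFallback logical per sample, TRUE where all masking deltas
#'   were zero and the uniform vector 1/p was substituted.
#' @export
setClass("ContributionSet",
         representation(omega = "matrix", eps = "numeric",
                        geneIds = "character", sampleIds = "character",
                        type = "character", uniformFallback = "logical"))

setValidity("ContributionSet", function(object) {
  msg <- character()
  if (ncol(object@omega) != length(object@geneIds))
    msg <- c(msg, "omega columns != geneIds")
  if (nrow(object@omega) != length(object@sampleIds))
    msg <- c(msg, "omega rows != sampleIds")
  if (any(object@omega < -1e-12)) msg <- c(msg, "negative contributions")
  s <- rowSums(object@omega)
  if (any(abs(s - 1) > 1e-6)) msg <- c(msg, "rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Aggregated per-drug gene scores
#'
#' Mean contribution of each gene across the labeled test samples of one
#' drug, scaled so the largest score equals 1.
#'
#' @slot geneIds gene identifiers.
#' @slot score numeric in `[0, 1]`, max exactly 1.
#' @slot drug drug name.
#' @slot nSamples number of samples averaged.
#' @export
setClass("DrugGeneScores",
         representation(geneIds = "character", score = "numeric",
                        drug = "character", nSamples = "integer"))

setValidity("DrugGeneScores", function(object) {
  msg <- character()
  if (length(object@score) != length(object@geneIds))
    msg <- c(msg, "score length != geneIds")
  if (length(object@score) &&
      abs(max(object@score) - 1) > 1e-8)
    msg <- c(msg, "maximum score must equal 1")
  if (any(object@score < 0)) msg <- c(msg, "scores must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Knee-point detection result
#'
#' The knee (point of maximum curvature) of a non-increasing score curve,
#' located as the point farthest above the line joining the curve's
#' endpoints after rescaling both axes to `[0, 1]`. Genes at ranks
#' `1..knee` form the selected panel (inclusive cutoff).
#'
#' @slot scores sorted (non-increasing) scores.
#' @slot geneIds identifiers in rank order (may be empty).
#' @slot kneeIndex integer rank of the knee, `NA` when no knee exists.
#' @slot hasKnee logical.
#' @slot diffCurve the normalized difference curve used for detection.
#' @slot selected gene identifiers at ranks `1..kneeIndex`.
#' @export
setClass("KneeResult",
         representation(scores = "numeric", geneIds = "character",
                        kneeIndex = "integer", hasKnee = "logical",
                        diffCurve = "numeric", selected = "character"))

#' Synthetic paired-cohort dataset
#'
#' Ground-truth-bearing source/target cohorts produced by
#' [simulateCohorts()]: a labeled source cohort with continuous response, a
#' labeled target cohort with binary sensitive/resistant labels, an
#' unlabeled target-domain pool for normalization, and the generative truth
#' (signal genes, coefficients, per-gene domain-shift offsets and scales,
#' noise draws, threshold, seed).
#'
#' @slot source,target,pool [GeneExpression-class] cohorts.
#' @slot sourceResponse named numeric continuous labels (ln IC50-like).
#' @slot targetLabels named character `"sensitive"`/`"resistant"`.
#' @slot targetResponse named numeric latent continuous response of target
#'   samples (the quantity the binary labels threshold).
#' @slot truth list of generative parameters.
#' @export
setClass("SyntheticDataset",
         representation(source = "GeneExpression",
                        sourceResponse = "numeric",
                        target = "GeneExpression",
                        targetLabels = "character",
                        targetResponse = "numeric",
                        pool = "GeneExpression",
                        truth = "list"))
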