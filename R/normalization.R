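# Gene-wise z-scoring. The population standard deviation (ddof = 0) is used
# everywhere so source- and target-fitted statistics are on the same
# convention.

popSd <- function(v) sqrt(colMeans(sweep(v, 2, colMeans(v))^2))

newNormalizerStats <- function(v, mode, referencePool) {
  mu <- colMeans(v)
  sigma <- popSd(v)
  flagged <- sigma == 0
  methods::new("NormalizerStats", geneIds = colnames(v), mu = unname(mu),
               sigma = unname(sigma), flagged = unname(flagged),
               mode = mode, referencePool = referencePool)
}

#' Fit gene-wise z-score statistics on a cohort
#'
#' Computes each gene's mean and population standard deviation over all
#' samples of `x`. Zero-variance genes are flagged (and later scaled by 1
#' rather than dropped, keeping gene sets aligned across cohorts).
#'
#' @param x a [GeneExpression-class] object (log-scale or
#'   platform-normalized).
#' @param mode which normalizer the statistics will serve; defaults to
#'   `"train_norm"` for a source-fitted z-score.
#' @return a [NormalizerStats-class] object.
#' @export
fitZscore <- function(x, mode = c("train_norm", "test_norm",
                                  "tissue_informed")) {
  mode <- match.arg(mode)
  stopifnot(methods::is(x, "GeneExpression"))
  v <- exprValues(x)
  if (nrow(v) < 2) stop("need at least 2 samples to fit z-score statistics")
  newNormalizerStats(v, mode,
                     list(cohort = domainOf(x), nSamples = nrow(v),
                          sampleIds = rownames(v)))
}

#' Fit the tissue-informed normalizer
#'
#' Fits per-gene statistics on an unlabeled target-domain pool restricted to
#' the drug's target tissues (the tissues of the patients who actually
#' received the drug), excluding any samples that appear in the evaluation
#' set. Target samples normalized with these statistics are placed on the
#' same scale as the z-scored source cohort without touching their labels.
#'
#' @param pool an unlabeled target-domain [GeneExpression-class] carrying
#'   tissue labels.
#' @param targetTissues character set of target tissues for the drug.
#' @param excludeSamples sample identifiers to leave out of the fit
#'   (typically the labeled evaluation samples).
#' @return a [NormalizerStats-class] with `mode = "tissue_informed"`; the
#'   `referencePool` slot records the tissue set and exclusions.
#' @export
fitTissueInformed <- function(pool, targetTissues,
                              excludeSamples = character()) {
  stopifnot(methods::is(pool, "GeneExpression"))
  tissues <- tissueOf(pool)
  if (is.null(tissues))
    stop("pool carries no tissue labels; tissue-informed fit impossible")
  targetTissues <- unique(as.character(targetTissues))
  missing <- setdiff(targetTissues, unique(tissues))
  if (length(missing))
    warning("target tissue(s) absent from the pool: ",
            paste(missing, collapse = ", "))
  keep <- tissues %in% targetTissues & !(sampleIds(pool) %in% excludeSamples)
  if (!any(keep))
    stop("reference pool is empty after tissue filter and exclusions")
  v <- exprValues(pool)[keep, , drop = FALSE]
  newNormalizerStats(v, "tissue_informed",
                     list(cohort = domainOf(pool), nSamples = nrow(v),
                          sampleIds = rownames(v),
                          targetTissues = targetTissues,
                          excludedSamples = as.character(excludeSamples)))
}

#' Apply fitted normalization statistics to a cohort
#'
#' Z-scores every gene of `x` with the supplied statistics:
#' `(value - mu) / sigma` per gene. Flagged zero-variance genes are centered
#' only (sigma treated as 1).
#'
#' @param x a [GeneExpression-class] object.
#' @param stats a [NormalizerStats-class]; its gene set must equal that of
#'   `x`.
#' @return the normalized [GeneExpression-class] (units `"zscore"`).
#' @export
applyNormalizer <- function(x, stats) {
  stopifnot(methods::is(x, "GeneExpression"),
            methods::is(stats, "NormalizerStats"))
  miss <- setdiff(geneIds(x), stats@geneIds)
  extra <- setdiff(stats@geneIds, geneIds(x))
  if (length(miss) || length(extra))
    stop("gene sets differ between matrix and normalizer; missing from ",
         "normalizer: ", paste(head(miss, 5), collapse = ", "),
         if (length(extra)) paste0("; missing from matrix: ",
                                   paste(head(extra, 5), collapse = ", ")))
  idx <- match(geneIds(x), stats@geneIds)
  mu <- stats@mu[idx]
  sigma <- ifelse(stats@flagged[idx], 1, stats@sigma[idx])
  v <- sweep(sweep(exprValues(x), 2, mu), 2, sigma, "/")
  geneExpression(v, domain = domainOf(x), tissue = tissueOf(x),
                 units = "zscore",
                 transforms = c(transformsOf(x),
                                paste0("zscore:", stats@mode)))
}

#' Z-score drug response labels
#'
#' Drug-wise z-scoring of continuous ln IC50 labels with the population
#' standard deviation, returning the normalized values together with the
#' fitted [LabelNormalizer-class] for the inverse transform.
#'
#' @param values numeric ln IC50 values (at least two distinct).
#' @param drug drug name.
#' @return list with `values` (normalized) and `normalizer`.
#' @seealso [denormalizeLabels()]
#' @export
normalizeLabels <- function(values, drug = "drug") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 label values")
  if (!all(is.finite(values))) stop("labels must be finite")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) stop("labels are constant; cannot z-score")
  nrm <- methods::new("LabelNormalizer", drug = drug, mu = mu, sigma = sigma)
  list(values = (values - mu) / sigma, normalizer = nrm)
}

#' Map normalized predictions back to the ln IC50 scale
#'
#' @param values numeric values on the z-scored label scale.
#' @param normalizer a [LabelNormalizer-class].
#' @return numeric values on the original label scale.
#' @export
denormalizeLabels <- function(values, normalizer) {
  stopifnot(methods::is(normalizer, "LabelNormalizer"))
  values * normalizer@sigma + normalizer@mu
}

#' Serialize normalizer statistics
#'
#' Writes a delimited table (gene, mu, sigma, flagged) plus a JSON
#' provenance header describing the reference pool; [readNormalizerStats()]
#' restores the object.
#'
#' @param stats a [NormalizerStats-class].
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeNormalizerStats <- function(stats, path) {
  df <- data.frame(gene = stats@geneIds, mu = stats@mu, sigma = stats@sigma,
                   flagged = stats@flagged)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mode = stats@mode,
                            referencePool = stats@referencePool),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNormalizerStats
#' @export
readNormalizerStats <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  methods::new("NormalizerStats", geneIds = as.character(df$gene),
               mu = df$mu, sigma = df$sigma, flagged = as.logical(df$flagged),
               mode = meta$mode, referencePool = as.list(meta$referencePool))
}
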