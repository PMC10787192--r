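#' Samples-by-genes expression values
#' @param x a [GeneExpression-class] object.
#' @return numeric matrix with samples in rows and genes in columns.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Sample identifiers
#' @param x an object carrying samples.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Gene identifiers
#' @param x an object carrying genes.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Cohort domain tag
#' @param x a [GeneExpression-class] object.
#' @return `"source"` or `"target"`.
#' @export
setGeneric("domainOf", function(x) standardGeneric("domainOf"))

#' Per-sample tissue labels
#' @param x a [GeneExpression-class] object.
#' @return character vector, or NULL when the cohort carries no tissues.
#' @export
setGeneric("tissueOf", function(x) standardGeneric("tissueOf"))

#' Transforms already applied to a cohort
#' @param x a [GeneExpression-class] object.
#' @export
setGeneric("transformsOf", function(x) standardGeneric("transformsOf"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "GeneExpression",
          function(x) t(SummarizedExperiment::assay(x, "exprs")))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GeneExpression", function(x) colnames(x))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneExpression", function(x) rownames(x))

#' @rdname geneIds
#' @export
setMethod("geneIds", "NormalizerStats", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("geneIds", "TrainedPredictor", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("geneIds", "ContributionSet", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("geneIds", "DrugGeneScores", function(x) x@geneIds)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ContributionSet", function(x) x@sampleIds)

#' @rdname domainOf
#' @export
setMethod("domainOf", "GeneExpression",
          function(x) S4Vectors::metadata(x)$domain)

#' @rdname tissueOf
#' @export
setMethod("tissueOf", "GeneExpression", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("tissue" %in% colnames(cd)) as.character(cd$tissue) else NULL
})

#' @rdname transformsOf
#' @export
setMethod("transformsOf", "GeneExpression",
          function(x) S4Vectors::metadata(x)$transforms)

setMethod("show", "GeneExpression", function(object) {
  cat(sprintf("GeneExpression: %d samples x %d genes [%s domain]\n",
              ncol(object), nrow(object),
              S4Vectors::metadata(object)$domain))
  tr <- S4Vectors::metadata(object)$transforms
  cat("  units:", S4Vectors::metadata(object)$units,
      "| transforms:", if (length(tr)) paste(tr, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(tissueOf(object)))
    cat("  tissues:", paste(unique(tissueOf(object)), collapse = ", "), "\n")
})

setMethod("show", "NormalizerStats", function(object) {
  cat(sprintf("NormalizerStats [%s]: %d genes, %d zero-variance flagged\n",
              object@mode, length(object@geneIds), sum(object@flagged)))
})

setMethod("show", "TrainedPredictor", function(object) {
  cat(sprintf(
    "TrainedPredictor: %d members, hidden [%s], dropout %.2f, %d genes\n",
    length(object@members), paste(object@hidden, collapse = ", "),
    object@dropout, length(object@geneIds)))
  hp <- object@hyperparams
  cat(sprintf("  epochs %s, batch %s, lr %s, base seed %d\n",
              hp$epochs, hp$batchSize, format(hp$lr), object@baseSeed))
})

setMethod("show", "ContributionSet", function(object) {
  cat(sprintf("ContributionSet (%s): %d samples x %d genes\n",
              object@type, nrow(object@omega), ncol(object@omega)))
  if (any(object@uniformFallback))
    cat("  uniform fallback in", sum(object@uniformFallback), "sample(s)\n")
})

setMethod("show", "DrugGeneScores", function(object) {
  ord <- order(object@score, decreasing = TRUE)
  cat(sprintf("DrugGeneScores for '%s' (%d genes, %d samples averaged)\n",
              object@drug, length(object@geneIds), object@nSamples))
  top <- head(ord, 5)
  cat("  top:", paste(sprintf("%s=%.3f", object@geneIds[top],
                              object@score[top]), collapse = " "), "\n")
})

setMethod("show", "KneeResult", function(object) {
  if (object@hasKnee)
    cat(sprintf("KneeResult: knee at rank %d of %d (panel of %d genes)\n",
                object@kneeIndex, length(object@scores),
                object@kneeIndex))
  else
    cat("KneeResult: no knee detected\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d source / %d target / %d pool samples, %d genes (%d signal)\n",
    ncol(object@source), ncol(object@target), ncol(object@pool),
    nrow(object@source), length(object@truth$signalGenes)))
})
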