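#' Knee-point detection on a ranked score curve
#'
#' Finds the point of maximum curvature of a non-increasing score curve —
#' the cutoff for the top-gene panel. Both axes are rescaled to `[0, 1]`;
#' the vertical difference between the line joining the endpoints
#' `(1, max score)` and `(n, min score)` and the curve is computed; the knee
#' is the local maximum of that difference curve with the largest
#' difference, ties broken toward the smallest rank (the more conservative,
#' smaller panel). A flat or collinear curve (maximum difference at or below
#' `tol`) yields no knee, as does `n < 3`.
#'
#' @param scores numeric scores sorted in non-increasing order.
#' @param geneIds optional gene identifiers aligned with `scores`.
#' @param tol flatness tolerance on the normalized difference curve.
#' @return a [KneeResult-class]; the selected panel is ranks `1..knee`
#'   (inclusive).
#' @examples
#' findKnee(c(1.0, 0.8, 0.6, 0.1, 0.08, 0.06))
#' @export
findKnee <- function(scores, geneIds = NULL, tol = 1e-9) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(n))
  if (length(geneIds) != n) stop("geneIds length must match scores")
  if (n >= 2 && any(diff(scores) > 1e-12))
    stop("scores must be sorted in non-increasing order")
  noKnee <- function() methods::new(
    "KneeResult", scores = scores, geneIds = as.character(geneIds),
    kneeIndex = NA_integer_, hasKnee = FALSE, diffCurve = numeric(),
    selected = character())
  if (n < 3) return(noKnee())
  rng <- scores[1] - scores[n]
  if (rng <= 0) return(noKnee())
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (scores - scores[n]) / rng
  d <- (1 - xs) - ys  # line from (0,1) to (1,0) minus the curve
  if (max(d) <= tol) return(noKnee())
  interior <- seq(2, n - 1)
  isLocalMax <- d[interior] >= d[interior - 1] & d[interior] >= d[interior + 1]
  cand <- interior[isLocalMax]
  if (!length(cand)) cand <- which.max(d)
  knee <- cand[which.max(d[cand])]  # which.max already prefers earliest tie
  methods::new("KneeResult", scores = scores, geneIds = as.character(geneIds),
               kneeIndex = as.integer(knee), hasKnee = TRUE, diffCurve = d,
               selected = as.character(geneIds[seq_len(knee)]))
}

#' Select the top-gene panel of a drug
#'
#' Sorts aggregated gene scores in decreasing order and cuts the ranking at
#' the knee of the score curve.
#'
#' @param scores a [DrugGeneScores-class].
#' @param tol flatness tolerance passed to [findKnee()].
#' @return a [KneeResult-class] over the sorted scores.
#' @export
selectPanel <- function(scores, tol = 1e-9) {
  stopifnot(methods::is(scores, "DrugGeneScores"))
  ord <- order(scores@score, decreasing = TRUE)
  findKnee(scores@score[ord], geneIds = scores@geneIds[ord], tol = tol)
}

#' Write a knee-selection result
#'
#' @param knee a [KneeResult-class].
#' @param path output TSV path (columns rank, gene, score, selected).
#' @return `path`, invisibly.
#' @export
writeKneeResult <- function(knee, path) {
  n <- length(knee@scores)
  sel <- logical(n)
  if (knee@hasKnee) sel[seq_len(knee@kneeIndex)] <- TRUE
  df <- data.frame(rank = seq_len(n), gene = knee@geneIds,
                   score = knee@scores, selected = sel)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
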