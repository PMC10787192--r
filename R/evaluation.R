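# Rank-based transfer evaluation: one-sided Mann-Whitney, Fisher's combined
# probability, precision at the k-th percentile, AUROC, and the Ward
# inter-domain distance in the latent space.

#' One-sided Mann-Whitney test that resistant predictions are higher
#'
#' Tests whether predicted ln IC50 values of resistant samples are
#' stochastically greater than those of sensitive samples. The exact
#' permutation distribution is enumerated when the pooled sample size is at
#' most 12 and no ties exist; otherwise the normal approximation with tie
#' correction is used.
#'
#' @param resistantPreds,sensitivePreds numeric predictions per group.
#' @return list with `U` (number of (resistant, sensitive) pairs where the
#'   resistant prediction is higher, ties counted half) and `p` (one-sided).
#' @export
mannWhitneyOneSided <- function(resistantPreds, sensitivePreds) {
  r <- as.numeric(resistantPreds)
  s <- as.numeric(sensitivePreds)
  if (!length(r) || !length(s)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(r, s)) > 0
  exact <- (length(r) + length(s)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(r, s, alternative = "greater", exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's method for combining independent P values
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom.
#'
#' @param pvalues numeric vector of P values in `(0, 1]`.
#' @return list with `statistic` (X), `df`, and `p` (combined).
#' @export
fisherCombined <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) stop("need at least one P value")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("P values must lie in (0, 1]")
  X <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = X, df = df, p = pchisq(X, df, lower.tail = FALSE))
}

#' Precision at the k-th percentile of the predictions
#'
#' The k-th percentile `t_k` of the predictions (linear-interpolation
#' convention) thresholds the cohort: samples predicted strictly below
#' `t_k` are called sensitive. Precision is the fraction of those calls
#' that are truly sensitive.
#'
#' @param preds numeric predicted ln IC50 values.
#' @param labels character `"sensitive"`/`"resistant"`, aligned with
#'   `preds`.
#' @param k percentile in `(0, 50]`.
#' @return list with `t_k`, `TP`, `FP`, `precision` (NA and flagged when no
#'   prediction falls below `t_k`) and `nBelow`.
#' @export
precisionAtPercentile <- function(preds, labels, k) {
  preds <- as.numeric(preds)
  labels <- as.character(labels)
  stopifnot(length(preds) == length(labels))
  if (!all(labels %in% c("sensitive", "resistant")))
    stop("labels must be 'sensitive' or 'resistant'")
  if (!is.numeric(k) || length(k) != 1 || k <= 0 || k > 50)
    stop("k must lie in (0, 50]")
  tk <- unname(quantile(preds, k / 100, type = 7))
  below <- preds < tk
  TP <- sum(below & labels == "sensitive")
  FP <- sum(below & labels == "resistant")
  list(t_k = tk, TP = TP, FP = FP,
       precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP),
       nBelow = sum(below))
}

#' Precision table over a percentile grid
#'
#' @param preds,labels as in [precisionAtPercentile()].
#' @param percentiles numeric percentiles in `(0, 50]`.
#' @return data.frame with one row per percentile.
#' @export
precisionTable <- function(preds, labels, percentiles = seq(5, 50, by = 5)) {
  rows <- lapply(percentiles, function(k) {
    pr <- precisionAtPercentile(preds, labels, k)
    data.frame(k = k, t_k = pr$t_k, TP = pr$TP, FP = pr$FP,
               precision = pr$precision)
  })
  do.call(rbind, rows)
}

#' AUROC of sensitive-versus-resistant discrimination
#'
#' Positive class is sensitive; the ranking score is the negated prediction
#' (a lower predicted ln IC50 means more sensitive), so a well-performing
#' model scores above 0.5. Computed by the midrank formula; ties count one
#' half.
#'
#' @param preds numeric predicted ln IC50 values.
#' @param labels character `"sensitive"`/`"resistant"`.
#' @return AUROC in `[0, 1]`.
#' @export
aurocScore <- function(preds, labels) {
  preds <- as.numeric(preds)
  labels <- as.character(labels)
  stopifnot(length(preds) == length(labels))
  pos <- labels == "sensitive"
  neg <- labels == "resistant"
  if (!any(pos) || !any(neg))
    stop("both classes must be present to compute AUROC")
  score <- -preds
  rk <- rank(score)
  n1 <- sum(pos)
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * sum(neg))
}

#' Ward merge distance between two groups of latent embeddings
#'
#' The increase in within-cluster sum of squares incurred by merging the
#' source and target groups:
#' `(n1 * n2 / (n1 + n2)) * ||c1 - c2||^2` with `c1`, `c2` the group
#' centroids. When lists of per-ensemble-member embeddings are supplied the
#' distance is computed per member and the mean with a 95 percent
#' percentile interval over members is reported.
#'
#' @param sourceEmb,targetEmb samples-by-d embedding matrices, or lists of
#'   such matrices (one per ensemble member).
#' @return for matrices, a single numeric distance; for lists, a list with
#'   `perMember`, `mean` and `ci` (2.5/97.5 percentiles).
#' @export
domainDistance <- function(sourceEmb, targetEmb) {
  if (is.list(sourceEmb) && !is.data.frame(sourceEmb)) {
    stopifnot(is.list(targetEmb), length(sourceEmb) == length(targetEmb))
    d <- mapply(domainDistance, sourceEmb, targetEmb)
    return(list(perMember = d, mean = mean(d),
                ci = unname(quantile(d, c(0.025, 0.975)))))
  }
  A <- as.matrix(sourceEmb)
  B <- as.matrix(targetEmb)
  if (!nrow(A) || !nrow(B)) stop("both groups must be non-empty")
  if (ncol(A) != ncol(B)) stop("embedding widths differ")
  n1 <- nrow(A); n2 <- nrow(B)
  cdiff <- colMeans(A) - colMeans(B)
  (n1 * n2 / (n1 + n2)) * sum(cdiff^2)
}

#' Full transfer evaluation report for one drug
#'
#' Bundles the one-sided Mann-Whitney test, AUROC and the precision table
#' for a set of target-cohort predictions with binary labels.
#'
#' @param preds named numeric predicted (normalized) ln IC50 values.
#' @param labels character `"sensitive"`/`"resistant"` aligned with
#'   `preds`.
#' @param percentiles percentile grid for the precision table.
#' @param drug drug name.
#' @return list of class `"evalReport"`: `drug`, `n`, `U`, `p`, `auroc`,
#'   `precision` (data.frame), plus the conventions used.
#' @export
evaluateTransfer <- function(preds, labels,
                             percentiles = seq(5, 50, by = 5),
                             drug = "drug") {
  labels <- as.character(labels)
  mw <- mannWhitneyOneSided(preds[labels == "resistant"],
                            preds[labels == "sensitive"])
  structure(list(drug = drug, n = length(preds),
                 nSensitive = sum(labels == "sensitive"),
                 nResistant = sum(labels == "resistant"),
                 U = mw$U, p = mw$p,
                 auroc = aurocScore(preds, labels),
                 precision = precisionTable(preds, labels, percentiles),
                 conventions = list(
                   percentile = "linear interpolation (type 7)",
                   threshold = "strictly below t_k",
                   aurocScore = "negated prediction, positive = sensitive")),
            class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("Transfer evaluation for '%s' (%d samples: %d sensitive, %d resistant)\n",
              x$drug, x$n, x$nSensitive, x$nResistant))
  cat(sprintf("  Mann-Whitney U = %.1f, one-sided P = %.4g\n", x$U, x$p))
  cat(sprintf("  AUROC = %.3f\n", x$auroc))
  cat("  precision@k:\n")
  print(x$precision, row.names = FALSE)
  invisible(x)
}
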