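#' Simulate paired source/target cohorts with planted signal genes
#'
#' Generates the statistical structure the transfer pipeline assumes: shared
#' per-tissue baseline expression across domains, a sparse set of signal
#' genes driving a continuous response, Gaussian sample noise, and a
#' per-gene affine (offset + scale) technical shift applied to the target
#' domain. The target cohort receives binary labels by thresholding its
#' latent continuous response at a quantile; an unlabeled pool is drawn from
#' the same target-domain distributions with disjoint sample identifiers.
#' Because the shift is affine per gene, gene-wise z-scoring against a pool
#' drawn from the target distribution aligns the domains by construction —
#' the regime the tissue-informed normalizer exploits. A non-affine "hard"
#' mode (`nonlinearShift = TRUE`) warps target values through a monotone
#' nonlinearity instead, where per-gene affine alignment is no longer exact.
#'
#' @param nSource,nTarget,nPool sample counts per cohort.
#' @param nGenes,nSignal total genes and planted signal genes
#'   (`nSignal <= nGenes`).
#' @param nTissues number of tissues; per-tissue gene baselines are drawn
#'   once and shared across domains, and every sample is assigned a tissue
#'   uniformly.
#' @param nTargetTissues number of tissues (out of `nTissues`) in which the
#'   simulated drug is administered: labeled target samples are drawn only
#'   from this subset, while the source cohort and the unlabeled pool span
#'   all tissues (the pool is filtered to the drug's tissues at
#'   normalization time). Defaults to all tissues.
#' @param shiftMagnitude additive offset applied to a random half of the
#'   genes in the target domain (0 disables the shift).
#' @param scaleRange range of per-gene multiplicative shift factors for the
#'   target domain; the default `c(1, 1)` disables scaling.
#' @param noiseSd standard deviation of the Gaussian noise on the response.
#' @param coefRange magnitude range of signal-gene coefficients (signs
#'   random).
#' @param nonlinearResponse add a quadratic signal-gene term to the
#'   response.
#' @param nonlinearShift apply a non-affine distortion to the target
#'   domain instead of the affine shift (the regime where per-gene
#'   z-scoring degrades).
#' @param thresholdQuantile target samples with latent response below this
#'   quantile are labeled sensitive; must lie in (0, 1).
#' @param seed integer seed; the same seed reproduces the dataset
#'   bit-exactly.
#' @return a [SyntheticDataset-class].
#' @examples
#' d <- simulateCohorts(nSource = 40, nTarget = 20, nPool = 20,
#'                      nGenes = 30, nSignal = 3, seed = 7)
#' d
#' @export
simulateCohorts <- function(nSource = 500L, nTarget = 100L, nPool = 200L,
                            nGenes = 200L, nSignal = 10L, nTissues = 3L,
                            nTargetTissues = nTissues,
                            shiftMagnitude = 2.0, scaleRange = c(1, 1),
                            noiseSd = 0.1, coefRange = c(0.5, 1.5),
                            nonlinearResponse = FALSE,
                            nonlinearShift = FALSE,
                            thresholdQuantile = 0.5, seed = 1L) {
  if (nSignal > nGenes) stop("nSignal must not exceed nGenes")
  if (any(c(nSource, nTarget, nPool, nGenes, nTissues) < 1))
    stop("all counts must be positive")
  if (thresholdQuantile <= 0 || thresholdQuantile >= 1)
    stop("thresholdQuantile must lie in (0, 1)")
  if (nTargetTissues < 1 || nTargetTissues > nTissues)
    stop("nTargetTissues must lie in 1..nTissues")
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(nGenes))
  tissues <- paste0("tissue", seq_len(nTissues))
  tissueMeans <- matrix(rnorm(nTissues * nGenes), nTissues, nGenes,
                        dimnames = list(tissues, genes))

  signalIdx <- sort(sample.int(nGenes, nSignal))
  w <- runif(nSignal, coefRange[1], coefRange[2]) *
    sample(c(-1, 1), nSignal, replace = TRUE)

  shifted <- if (shiftMagnitude != 0)
    sort(sample.int(nGenes, max(1L, floor(nGenes / 2)))) else integer()
  delta <- numeric(nGenes)
  delta[shifted] <- shiftMagnitude
  scaleF <- runif(nGenes, scaleRange[1], scaleRange[2])

  drugTissues <- tissues[seq_len(nTargetTissues)]

  drawBase <- function(n, prefix, from = tissues) {
    ti <- sample(from, n, replace = TRUE)
    base <- tissueMeans[ti, , drop = FALSE] +
      matrix(rnorm(n * nGenes), n, nGenes)
    rownames(base) <- sprintf("%s%04d", prefix, seq_len(n))
    colnames(base) <- genes
    list(base = base, tissue = ti)
  }
  respond <- function(base, noise) {
    y <- drop(base[, signalIdx, drop = FALSE] %*% w)
    if (nonlinearResponse)
      y <- y + drop((base[, signalIdx, drop = FALSE]^2) %*% (0.3 * w))
    y + noise
  }
  shiftDomain <- function(base) {
    if (nonlinearShift)
      return(sweep(sign(base) * abs(base)^1.5, 2, delta, "+"))
    sweep(sweep(base, 2, scaleF, "*"), 2, delta, "+")
  }

  src <- drawBase(nSource, "src")
  srcNoise <- rnorm(nSource, 0, noiseSd)
  ySource <- setNames(respond(src$base, srcNoise), rownames(src$base))

  tgt <- drawBase(nTarget, "tgt", from = drugTissues)
  tgtNoise <- rnorm(nTarget, 0, noiseSd)
  yTarget <- setNames(respond(tgt$base, tgtNoise), rownames(tgt$base))
  thr <- unname(quantile(yTarget, thresholdQuantile, type = 7))
  labels <- setNames(ifelse(yTarget < thr, "sensitive", "resistant"),
                     names(yTarget))

  pool <- drawBase(nPool, "pool")

  mk <- function(values, domain, tissue)
    geneExpression(values, domain = domain, tissue = tissue, units = "log2",
                   transforms = "log2")

  methods::new(
    "SyntheticDataset",
    source = mk(src$base, "source", src$tissue),
    sourceResponse = ySource,
    target = mk(shiftDomain(tgt$base), "target", tgt$tissue),
    targetLabels = labels,
    targetResponse = yTarget,
    pool = mk(shiftDomain(pool$base), "target", pool$tissue),
    truth = list(signalGenes = genes[signalIdx], signalIdx = signalIdx,
                 coefficients = setNames(w, genes[signalIdx]),
                 noiseSd = noiseSd, delta = setNames(delta, genes),
                 scale = setNames(scaleF, genes),
                 shiftedGenes = genes[shifted],
                 tissueMeans = tissueMeans,
                 sourceNoise = setNames(srcNoise, names(ySource)),
                 targetNoise = setNames(tgtNoise, names(yTarget)),
                 sourceBase = src$base, targetBase = tgt$base,
                 drugTissues = drugTissues,
                 threshold = thr, thresholdQuantile = thresholdQuantile,
                 nonlinearResponse = nonlinearResponse,
                 nonlinearShift = nonlinearShift, seed = seed))
}

#' Tiny deterministic fixture dataset
#'
#' A small fixed-seed dataset (40 source, 20 target, 20 pool samples, 30
#' genes, 3 signal genes, 2 tissues) used throughout the unit tests: large
#' enough to exercise every pipeline stage, small enough to load in well
#' under a second.
#'
#' @return a [SyntheticDataset-class].
#' @export
makeFixture <- function() {
  simulateCohorts(nSource = 40L, nTarget = 20L, nPool = 20L, nGenes = 30L,
                  nSignal = 3L, nTissues = 2L, shiftMagnitude = 1.5,
                  scaleRange = c(1, 1), noiseSd = 0.2,
                  coefRange = c(1, 1), seed = 16L)
}

#' Write a synthetic dataset in the pipeline's file formats
#'
#' Writes the three cohorts via [writeExpression()], the continuous source
#' labels and binary target labels as TSVs, and the ground truth as JSON.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  stopifnot(methods::is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(dataset@source, file.path(dir, "source.tsv"))
  writeExpression(dataset@target, file.path(dir, "target.tsv"))
  writeExpression(dataset@pool, file.path(dir, "pool.tsv"))
  write.table(data.frame(sample_id = names(dataset@sourceResponse),
                         ln_ic50 = unname(dataset@sourceResponse)),
              file.path(dir, "source_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(dataset@targetLabels),
                         label = unname(dataset@targetLabels)),
              file.path(dir, "target_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- dataset@truth
  truth$tissueMeans <- NULL
  truth$sourceBase <- NULL
  truth$targetBase <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
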