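# Shared lazily-built objects, cached for the whole test run. The fixture is
# tiny; the "shared model" is a small ensemble trained once on it and reused
# by every test that needs a realistic trained predictor.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

sharedFixture <- function() memo("fixture", makeFixture())

# fixture cohorts normalized under the tissue-informed mode + z-scored labels
sharedNormalized <- function() memo("normalized", {
  d <- sharedFixture()
  nz <- drtransfer:::normalizeCohorts(pipelineConfig(), d@source, d@target,
                                      d@pool)
  ln <- normalizeLabels(unname(d@sourceResponse), drug = "fixture-drug")
  list(data = d, source = nz$source, target = nz$target,
       sourceStats = nz$sourceStats, targetStats = nz$targetStats,
       y = ln$values, labelNormalizer = ln$normalizer)
})

sharedModel <- function() memo("model", {
  nz <- sharedNormalized()
  trainEnsemble(nz$source, nz$y,
                hyperparams = list(lr = 1e-3, batchSize = 16L, epochs = 60L),
                K = 3L, baseSeed = 7L, hidden = c(32L, 16L, 8L),
                labelNormalizer = nz$labelNormalizer)
})

popSd <- function(x) sqrt(mean((x - mean(x))^2))

# exhaustive-enumeration oracle for the one-sided Mann-Whitney P:
# all label arrangements of the pooled values, P = fraction with U >= observed
mwEnumerate <- function(resistant, sensitive) {
  pool <- c(resistant, sensitive)
  n1 <- length(resistant)
  Ustat <- function(r, s) sum(outer(r, s, ">")) + 0.5 * sum(outer(r, s, "=="))
  obs <- Ustat(resistant, sensitive)
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2, function(ix) Ustat(pool[ix], pool[-ix]))
  mean(us >= obs - 1e-12)
}

# quick constructor for a hand-weighted single network wrapped as an ensemble
handPredictor <- function(weightsList, biasesList, geneIds) {
  member <- drtransfer:::newDenseNet(weightsList, biasesList, "linear")
  methods::new("TrainedPredictor", members = list(member),
               hidden = vapply(weightsList[-length(weightsList)], ncol,
                               integer(1)),
               dropout = 0, hyperparams = list(lr = 0, batchSize = 1L,
                                               epochs = 0L),
               geneIds = geneIds, labelNormalizer = NULL, baseSeed = 0L)
}
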