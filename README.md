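# drtransfer

Preclinical-to-clinical drug response transfer with tissue-informed
normalization, and biomarker identification by masking-based gene
attribution.

## The problem

Anti-cancer drug sensitivity can be measured at scale in cancer cell lines
(a continuous ln IC50 per cell line and drug), but labeled patient tumors
are scarce. `drtransfer` trains a regression model **only on cell-line
expression** and transfers it to tumor expression, then explains the
trained model to nominate a compact panel of response-associated genes. It
is aimed at computational biologists studying drug response who need (a) a
transfer pipeline that survives the cell-line-to-tumor domain shift and
(b) gene-level attributions with a principled cutoff — plus a synthetic
cohort generator with planted ground truth so every stage can be validated
end to end.

## The method

**Phase 1 — prediction.** Source (cell-line) expression is z-scored
gene-wise and labels drug-wise. Each tumor sample is normalized against an
*unlabeled pool* of target-domain samples restricted to the drug's target
tissues T<sub>D</sub> (the tissues of patients who received the drug),
excluding the evaluation samples:

    x_i = (x~_i − μ_{i,T_D}) / σ_{i,T_D}

For a per-gene affine domain shift this provably places tumors on the
source scale. A dense network (hidden layers 512/256/128, ReLU, dropout
0.2 before the linear output) is trained with MSE on normalized ln IC50;
hyperparameters come from a 5-fold cross-validated grid search (≤ 1000
epochs, early stopping at patience 30), and K = 10 seed-ensemble members
are averaged.

**Phase 2 — attribution.** For every training sample, zeroing out gene i
(in normalized space) changes the squared prediction error by
Δε<sub>i</sub>; the normalized, clamped increases form a per-sample
contribution vector on the probability simplex. Ten explainer networks
(2 × 512 hidden units, softmax output) are distilled from these targets by
minimizing KL(target ‖ prediction); their elementwise median scores the
test samples in one forward pass. Per-drug gene scores are the mean over
labeled test samples, rescaled to max 1, and the panel is cut at the
**knee** (point of maximum curvature) of the ranked score curve.

**Evaluation.** One-sided Mann–Whitney (resistant predictions greater),
Fisher's combined probability across drugs, precision at the k-th
percentile, AUROC (positive = sensitive, score = −prediction), and the
Ward merge distance between source and target cohorts in the latent space
of the encoder.

## Worked example

```r
library(drtransfer)

d <- simulateCohorts(nSource = 300, nTarget = 60, nPool = 100, nGenes = 100,
                     nSignal = 5, shiftMagnitude = 2, seed = 1)
cfg <- pipelineConfig(drug = "demo-drug", hidden = c(128L, 64L, 32L),
                      K = 3L, nExplainers = 3L,
                      grid = data.frame(lr = 1e-3, batchSize = 64L),
                      epochs = 30L, explainerEpochs = 40L,
                      explainerHidden = 128L, baseSeed = 1L)
res <- runPipeline(cfg, d@source, d@sourceResponse, d@target,
                   targetLabels = d@targetLabels, pool = d@pool)
res$eval
res$knee
sum(d@truth$signalGenes %in% res$knee@selected)
```

prints (about 30 s on one CPU):

```
Transfer evaluation for 'demo-drug' (60 samples: 30 sensitive, 30 resistant)
  Mann-Whitney U = 797.0, one-sided P = 1.505e-07
  AUROC = 0.886
  precision@k:
  k         t_k TP FP precision
  5 -0.96592213  3  0 1.0000000
 10 -0.88994350  6  0 1.0000000
 ...
 50  0.06077450 25  5 0.8333333
KneeResult: knee at rank 8 of 100 (panel of 8 genes)
[1] 5
```

Read: tumor samples labeled resistant received significantly higher
predicted ln IC50 than sensitive ones (one-sided P ≈ 1.5e−7); ranking by
predicted sensitivity discriminates the classes with AUROC 0.89, and the
most confident calls (bottom percentiles of predicted ln IC50) are almost
all truly sensitive. The knee of the contribution-score curve selects an
8-gene panel that contains all 5 planted signal genes.

A thin CLI over the same functions ships in
`inst/scripts/drtransfer-cli.R` (subcommands `simulate`, `run`, `knee`,
`evaluate`).

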