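## Independent brute-force oracles, kept deliberately separate from the
## package implementations they check.

## Tukey median polish by explicit alternating row/column median sweeps.
oracleMedianPolish <- function(block, maxiter = 1000L, eps = 1e-12) {
  overall <- 0
  rowEff <- rep(0, nrow(block))
  colEff <- rep(0, ncol(block))
  res <- block
  for (i in seq_len(maxiter)) {
    rmed <- apply(res, 1L, median)
    res <- res - rmed
    rowEff <- rowEff + rmed
    cmed <- median(rowEff)
    rowEff <- rowEff - cmed
    overall <- overall + cmed
    cmed <- apply(res, 2L, median)
    res <- sweep(res, 2L, cmed)
    colEff <- colEff + cmed
    rmed <- median(colEff)
    colEff <- colEff - rmed
    overall <- overall + rmed
    if (sum(abs(rmed)) + sum(abs(cmed)) < eps) break
  }
  list(overall = overall, row = rowEff, col = colEff, residuals = res)
}

## SAM d-statistic straight from its definition, one feature at a time.
oracleSamD <- function(m, labels, s0) {
  labels <- factor(labels)
  g1 <- labels == levels(labels)[1L]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  apply(m, 1L, function(x) {
    s <- sqrt((1 / n1 + 1 / n2) *
                (sum((x[g1] - mean(x[g1]))^2) +
                   sum((x[g2] - mean(x[g2]))^2)) / (n1 + n2 - 2))
    (mean(x[g1]) - mean(x[g2])) / (s + s0)
  })
}

## Benjamini-Hochberg step-up q-values by the textbook cumulative-minimum.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

## Cell-mean difference-in-differences: the interaction CeT:doH computed
## directly from the four tissue:dose cell means.
oracleDiD <- function(m, sheet) {
  cellMean <- function(tissue, dose)
    rowMeans(m[, sheet$tissue == tissue & sheet$dose == dose, drop = FALSE])
  (cellMean("T", "H") - cellMean("P", "H")) -
    (cellMean("T", "sham") - cellMean("P", "sham"))
}

## Small Table-1/Table-2-shaped sample sheets built in code.
table1Sheet <- function() smokeSig::sampleSheet(
  simulateMrnaExperiment(mrnaSimConfig(nFeatures = 2L, nInteractionL = 0L,
                                       nInteractionM = 0L,
                                       nInteractionH = 0L, seed = 1L)))

mirnaDirectConfig <- function(seed, nFeatures = 260L,
                              figure8Counts = defaultFigure8Counts(),
                              effectSize = 1, residualSd = 0.25, ...) {
  mirnaSimConfig(nFeatures = nFeatures, figure8Counts = figure8Counts,
                 effectSize = effectSize, residualSd = residualSd,
                 probesPerFeature = 1L, probeSd = 0, probeAffinitySd = 0,
                 outlierArrays = 0L, absentFraction = 0, seed = seed, ...)
}

## Feature-level log2 matrix of a probe-level simulated miRNA experiment
## generated with one probe per feature.
mirnaLog2 <- function(se) {
  m <- log2(SummarizedExperiment::assay(se, "raw"))
  rownames(m) <- SummarizedExperiment::rowData(se)$feature_id
  m
}
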