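## Synthetic mRNA- and miRNA-like datasets with planted ground truth.
##
## The generators emulate the study design the downstream analyses assume:
## tumor (T) and surrounding parenchyma (P) arrays across four smoke-exposure
## dose groups (sham, L = MS-75, M = MS-150, H = MS-300), with effects planted
## additively on the log2 scale through the same 8-term design the model
## fits.

.FIG8_LABELS <- c(
  "parenchyma-only/exposure-effect-only",
  "parenchyma-only/tissue-effect-vanishes",
  "parenchyma-only/tumor-high",
  "parenchyma-only/tumor-low",
  "parenchyma-only/mixed",
  "tumor-only",
  "both/discordant",
  "both/concordant"
)

.MRNA_LABELS <- c("interaction-L", "interaction-M", "interaction-H")

#' The terminal taxonomy of the miRNA subset tree
#'
#' Level 1 splits interaction-significant miRNAs by where the smoke effect is
#' seen (parenchyma only, tumor only, or both tissues; "both" subdivides into
#' discordant/concordant smoke-effect signs). Level 2 subdivides the
#' parenchyma-only branch by the tumor-vs-parenchyma tissue effect in sham and
#' under exposure, and Level 3 splits the miRNAs with a tissue effect in both
#' conditions by its sign pattern (tumor-high, tumor-low, or mixed).
#'
#' @return character vector of the eight terminal category labels.
#' @export
figure8Categories <- function() .FIG8_LABELS

#' Reported terminal-category membership counts
#'
#' The per-category membership counts of the 70 interaction-significant
#' miRNAs reported in the study (62 parenchyma-only = 3 exposure-effect-only
#' + 35 tissue-effect-vanishes + 5 tumor-high + 17 tumor-low + 2 mixed;
#' 3 tumor-only; 5 both = 4 discordant + 1 concordant). Used as the default
#' planted counts of the miRNA simulator.
#'
#' @return named integer vector over \code{\link{figure8Categories}}.
#' @export
defaultFigure8Counts <- function() {
  setNames(c(3L, 35L, 5L, 17L, 2L, 3L, 4L, 1L), .FIG8_LABELS)
}

#' Planted coefficient template for an effect class
#'
#' Maps an effect-class label to the 8-vector of planted model coefficients
#' (intercept always 0; the per-feature baseline is added separately). The
#' miRNA templates are constructed so the four classification contrasts
#' (smoke-in-tumor = doH + CeT:doH, smoke-in-parenchyma = doH,
#' tissue-in-sham = CeT, tissue-under-smoke = CeT + CeT:doH) are exactly zero
#' where the category demands a null and +/- the effect size elsewhere.
#'
#' @param label one of \code{\link{figure8Categories}}, "interaction-L/M/H",
#'   "null", or "absent".
#' @param effect log2 effect size (>= 0).
#' @return named numeric vector over the eight model terms.
#' @export
plantedBetas <- function(label, effect) {
  b <- setNames(numeric(8L), .TERMS)
  e <- effect
  switch(label,
    "null" = ,
    "absent" = b,
    "interaction-L" = { b["CeT:doL"] <- e; b },
    "interaction-M" = { b["CeT:doM"] <- e; b },
    "interaction-H" = { b["CeT:doH"] <- e; b },
    "parenchyma-only/exposure-effect-only" = {
      b["doH"] <- e; b["CeT:doH"] <- -e; b
    },
    "parenchyma-only/tissue-effect-vanishes" = {
      b["CeT"] <- e; b["doH"] <- e; b["CeT:doH"] <- -e; b
    },
    "parenchyma-only/tumor-high" = {
      b["CeT"] <- 2 * e; b["doH"] <- e; b["CeT:doH"] <- -e; b
    },
    "parenchyma-only/tumor-low" = {
      b["CeT"] <- -e; b["doH"] <- e; b["CeT:doH"] <- -e; b
    },
    "parenchyma-only/mixed" = {
      b["CeT"] <- e; b["doH"] <- 2 * e; b["CeT:doH"] <- -2 * e; b
    },
    "tumor-only" = { b["CeT:doH"] <- e; b },
    "both/discordant" = { b["doH"] <- -e; b["CeT:doH"] <- 2 * e; b },
    "both/concordant" = { b["doH"] <- e; b["CeT:doH"] <- e; b },
    stop("unknown effect-class label: ", label)
  )
}

.mrnaGroupSizes <- function() {
  data.frame(
    tissue = rep(c("P", "T"), each = 4L),
    dose = rep(.DOSES, 2L),
    n = c(2L, 2L, 5L, 5L, 8L, 8L, 6L, 9L),
    nAnimals = c(2L, 2L, 5L, 5L, 8L, 8L, 6L, 9L),
    stringsAsFactors = FALSE
  )
}

.mirnaGroupSizes <- function() {
  data.frame(
    tissue = rep(c("P", "T"), each = 4L),
    dose = rep(.DOSES, 2L),
    n = c(10L, 10L, 10L, 10L, 8L, 7L, 6L, 9L),
    ## parenchyma groups reach 10 arrays by re-hybridizing two animals
    nAnimals = c(8L, 8L, 8L, 8L, 8L, 7L, 6L, 9L),
    stringsAsFactors = FALSE
  )
}

.newSimConfig <- function(nFeatures, groupSizes, effectClasses, baselineRange,
                          residualSd, probesPerFeature, probeSd,
                          probeAffinitySd, outlierArrays, absentFraction,
                          seed) {
  new("SimConfig",
      nFeatures = as.integer(nFeatures),
      groupSizes = groupSizes,
      effectClasses = effectClasses,
      baselineRange = as.numeric(baselineRange),
      residualSd = as.numeric(residualSd),
      probesPerFeature = as.integer(probesPerFeature),
      probeSd = as.numeric(probeSd),
      probeAffinitySd = as.numeric(probeAffinitySd),
      outlierArrays = as.integer(outlierArrays),
      absentFraction = as.numeric(absentFraction),
      seed = as.integer(seed))
}

#' Simulation configuration for an mRNA-like experiment
#'
#' Defaults reproduce the study's gene-expression arm: the Table-1 design
#' (parenchyma 2/2/5/5, tumor 8/8/6/9 arrays over sham/L/M/H), 20,000
#' features, and 1/2/269 genes planted with a tissue-by-dose interaction in
#' the L/M/H dose groups respectively. Planted interaction signs alternate
#' (up/down) within each class.
#'
#' @param nFeatures number of genes.
#' @param nInteractionL,nInteractionM,nInteractionH planted interacting gene
#'   counts per dose group.
#' @param effectSize absolute planted interaction coefficient, log2 units.
#' @param baselineRange,residualSd,seed see \code{\linkS4class{SimConfig}}.
#' @param groupSizes design-cell sizes (defaults to the Table-1 design).
#' @return a validated \code{\linkS4class{SimConfig}}.
#' @export
mrnaSimConfig <- function(nFeatures = 20000L,
                          nInteractionL = 1L,
                          nInteractionM = 2L,
                          nInteractionH = 269L,
                          effectSize = 2,
                          baselineRange = c(6, 12),
                          residualSd = 0.25,
                          groupSizes = .mrnaGroupSizes(),
                          seed = 1L) {
  ec <- data.frame(
    label = .MRNA_LABELS,
    n = as.integer(c(nInteractionL, nInteractionM, nInteractionH)),
    effect = effectSize,
    stringsAsFactors = FALSE
  )
  ec <- ec[ec$n > 0L, , drop = FALSE]
  .newSimConfig(nFeatures, groupSizes, ec, baselineRange, residualSd,
                probesPerFeature = 1L, probeSd = 0, probeAffinitySd = 0,
                outlierArrays = 0L, absentFraction = 0, seed = seed)
}

#' Simulation configuration for a miRNA-like experiment
#'
#' Defaults reproduce the study's miRNA arm: the Table-2 design (parenchyma
#' 10/10/10/10, tumor 8/7/6/9 arrays), 274 raw features of which 14 (about
#' 5\%) are planted "absent" so that detection-call filtering leaves the
#' reported 260, probe-level quadruplicates, one planted low-correlation
#' outlier array (an extra technical replicate whose values are permuted
#' within the array), and the reported Figure-8 terminal-category memberships
#' planted at 4 residual SDs.
#'
#' @param nFeatures number of raw miRNA features.
#' @param figure8Counts named planted counts over
#'   \code{\link{figure8Categories}}.
#' @param effectSize base absolute planted effect, log2 units.
#' @param probesPerFeature,probeSd,probeAffinitySd probe-level replication
#'   and noise.
#' @param outlierArrays,absentFraction planted QC defects.
#' @param baselineRange,residualSd,groupSizes,seed see
#'   \code{\linkS4class{SimConfig}}.
#' @return a validated \code{\linkS4class{SimConfig}}.
#' @export
mirnaSimConfig <- function(nFeatures = 274L,
                           figure8Counts = defaultFigure8Counts(),
                           effectSize = 1,
                           baselineRange = c(6, 12),
                           residualSd = 0.25,
                           probesPerFeature = 4L,
                           probeSd = 0.1,
                           probeAffinitySd = 0.25,
                           outlierArrays = 1L,
                           absentFraction = 14 / 274,
                           groupSizes = .mirnaGroupSizes(),
                           seed = 1L) {
  stopifnot(all(names(figure8Counts) %in% .FIG8_LABELS))
  ec <- data.frame(
    label = names(figure8Counts),
    n = as.integer(figure8Counts),
    effect = rep(effectSize, length.out = length(figure8Counts)),
    stringsAsFactors = FALSE
  )
  ec <- ec[ec$n > 0L, , drop = FALSE]
  .newSimConfig(nFeatures, groupSizes, ec, baselineRange, residualSd,
                probesPerFeature, probeSd, probeAffinitySd, outlierArrays,
                absentFraction, seed)
}

## Expand design-cell sizes into a per-array sample sheet. Arrays beyond
## nAnimals in a cell are technical replicates (re-hybridizations) of that
## cell's first animals.
.buildSheet <- function(gs) {
  gs <- gs[gs$n > 0L, , drop = FALSE]
  if (is.null(gs$nAnimals)) gs$nAnimals <- gs$n
  rows <- lapply(seq_len(nrow(gs)), function(i) {
    n <- gs$n[i]
    nA <- min(gs$nAnimals[i], n)
    animal <- c(seq_len(nA), seq_len(n - nA))
    data.frame(
      sample_id = sprintf("%s_%s_%02d", gs$tissue[i], gs$dose[i],
                          seq_len(n)),
      tissue = gs$tissue[i],
      dose = gs$dose[i],
      animal_id = sprintf("%s_%s_a%02d", gs$tissue[i], gs$dose[i], animal),
      is_replicate = seq_len(n) > nA,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.checkFullDesign <- function(gs) {
  gs <- gs[gs$n > 0L, , drop = FALSE]
  cells <- paste(gs$tissue, gs$dose, sep = ":")
  all8 <- as.vector(outer(.TISSUES, .DOSES, paste, sep = ":"))
  missing <- setdiff(all8, cells)
  if (length(missing))
    stop("empty design cell(s): ", paste(missing, collapse = ", "),
         "; the 8-term interaction model needs every tissue:dose cell")
  invisible(TRUE)
}

## Planted truth: class label and coefficient matrix for every feature.
.assignClasses <- function(nFeatures, effectClasses, nAbsent, prefix) {
  planted <- rep(effectClasses$label, effectClasses$n)
  nNull <- nFeatures - length(planted) - nAbsent
  if (nNull < 0)
    stop("planted effect classes plus absent features exceed nFeatures")
  classes <- c(planted, rep("absent", nAbsent), rep("null", nNull))
  ids <- sprintf("%s%05d", prefix, seq_len(nFeatures))
  B <- matrix(0, nFeatures, 8L, dimnames = list(ids, .TERMS))
  k <- 0L
  for (i in seq_len(nrow(effectClasses))) {
    lab <- effectClasses$label[i]
    tmpl <- plantedBetas(lab, effectClasses$effect[i])
    for (j in seq_len(effectClasses$n[i])) {
      k <- k + 1L
      ## interaction-only (mRNA) classes alternate sign; the Figure-8
      ## templates carry meaningful sign patterns and are used as-is
      s <- if (lab %in% .MRNA_LABELS && j %% 2L == 0L) -1 else 1
      B[k, ] <- s * tmpl
    }
  }
  list(ids = ids, classes = classes, B = B)
}

.truthFrame <- function(ids, classes, B, baseline) {
  tb <- B
  tb[, 1L] <- baseline
  tb[classes == "absent", 1L] <- NA_real_
  df <- DataFrame(feature_id = ids, true_class = classes)
  colnames(tb) <- sprintf("beta%d", 0:7)
  cbind(df, DataFrame(tb))
}

#' Simulate an mRNA-like expression experiment
#'
#' Draws per-feature baselines uniformly from \code{baselineRange}, applies
#' the planted coefficients through the coded 8-term design, and adds i.i.d.
#' Gaussian noise with SD \code{residualSd} -- all on the log2 scale.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config a \code{\linkS4class{SimConfig}}, e.g. from
#'   \code{\link{mrnaSimConfig}}.
#' @return a \code{SummarizedExperiment} with assay \code{"exprs"} (log2,
#'   features x samples), the sample sheet as \code{colData}, and the planted
#'   truth (class label and coefficients) as \code{rowData}.
#' @export
simulateMrnaExperiment <- function(config = mrnaSimConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .checkFullDesign(config@groupSizes)
  set.seed(config@seed)
  sheet <- .buildSheet(config@groupSizes)
  X <- buildDesignMatrix(sheet)
  tr <- .assignClasses(config@nFeatures, config@effectClasses,
                       nAbsent = 0L, prefix = "g")
  baseline <- runif(config@nFeatures, config@baselineRange[1L],
                    config@baselineRange[2L])
  mu <- baseline + tr$B %*% t(X)
  y <- mu + matrix(rnorm(length(mu), sd = config@residualSd),
                   nrow = nrow(mu))
  dimnames(y) <- list(tr$ids, sheet$sample_id)
  truth <- .truthFrame(tr$ids, tr$classes, tr$B, baseline)
  SummarizedExperiment(
    assays = list(exprs = y),
    rowData = truth,
    colData = DataFrame(sheet, row.names = sheet$sample_id),
    metadata = list(config = config)
  )
}

#' Simulate a raw probe-level miRNA-like experiment
#'
#' Expressed features follow the same log2 linear model as
#' \code{\link{simulateMrnaExperiment}}; each feature is measured by
#' \code{probesPerFeature} replicate probes carrying a fixed per-probe
#' affinity offset plus probe-level noise, and intensities are emitted on the
#' raw (exponentiated) scale. Planted "absent" features are drawn uniformly
#' from the low-intensity background (raw 1--4), below typical array
#' 5th-percentile detection thresholds. Planted outlier arrays are extra
#' technical-replicate hybridizations whose values are independently permuted
#' within the array, destroying their between-array correlation at unchanged
#' marginal distribution.
#'
#' @param config a \code{\linkS4class{SimConfig}}, e.g. from
#'   \code{\link{mirnaSimConfig}}.
#' @return a \code{SummarizedExperiment} with assay \code{"raw"} (probe x
#'   array intensities), probe-to-feature mapping as \code{rowData}, the
#'   sample sheet (with \code{planted_outlier} flags) as \code{colData}, and
#'   the feature-level truth table in \code{metadata(se)$truth}.
#' @export
simulateMirnaExperiment <- function(config = mirnaSimConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .checkFullDesign(config@groupSizes)
  set.seed(config@seed)

  sheet <- .buildSheet(config@groupSizes)
  nOut <- config@outlierArrays
  if (nOut > 0L) {
    src <- sheet[rep_len(seq_len(nrow(sheet)), nOut), , drop = FALSE]
    src$sample_id <- sprintf("%s_rep%02d", src$sample_id, seq_len(nOut))
    src$is_replicate <- TRUE
    sheet <- rbind(sheet, src)
  }
  sheet$planted_outlier <-
    seq_len(nrow(sheet)) > (nrow(sheet) - nOut)

  X <- buildDesignMatrix(sheet)
  nAbsent <- as.integer(round(config@absentFraction * config@nFeatures))
  tr <- .assignClasses(config@nFeatures, config@effectClasses,
                       nAbsent = nAbsent, prefix = "mir")
  expressed <- tr$classes != "absent"
  baseline <- runif(config@nFeatures, config@baselineRange[1L],
                    config@baselineRange[2L])

  mu <- baseline + tr$B %*% t(X)       # feature x array, log2
  v <- mu + matrix(rnorm(length(mu), sd = config@residualSd), nrow(mu))

  P <- config@probesPerFeature
  nF <- config@nFeatures
  nS <- nrow(sheet)
  affinity <- rnorm(nF * P, sd = config@probeAffinitySd)
  probeFeature <- rep(seq_len(nF), each = P)
  probeLog2 <- v[probeFeature, , drop = FALSE] + affinity +
    matrix(rnorm(nF * P * nS, sd = config@probeSd), nF * P, nS)
  raw <- 2^probeLog2
  ## absent features: background-level intensities, independent of design
  absProbes <- which(!expressed[probeFeature])
  raw[absProbes, ] <- matrix(runif(length(absProbes) * nS, 1, 4),
                             length(absProbes), nS)
  for (j in which(sheet$planted_outlier))
    raw[, j] <- raw[sample.int(nrow(raw)), j]

  probeIds <- sprintf("%s_p%d", tr$ids[probeFeature],
                      rep(seq_len(P), times = nF))
  dimnames(raw) <- list(probeIds, sheet$sample_id)
  truth <- .truthFrame(tr$ids, tr$classes, tr$B, baseline)
  SummarizedExperiment(
    assays = list(raw = raw),
    rowData = DataFrame(probe_id = probeIds,
                        feature_id = tr$ids[probeFeature],
                        row.names = probeIds),
    colData = DataFrame(sheet, row.names = sheet$sample_id),
    metadata = list(config = config, truth = truth)
  )
}

#' @describeIn accessors the per-sample sheet (tissue, dose, animal,
#'   replicate flag) of a simulated or assembled experiment.
#' @export
setMethod("sampleSheet", "SummarizedExperiment", function(object, ...) {
  as.data.frame(colData(object))
})

#' @describeIn accessors the planted truth table (feature id, true class,
#'   planted coefficients) of a simulated experiment.
#' @export
setMethod("truthTable", "SummarizedExperiment", function(object, ...) {
  if (!is.null(metadata(object)$truth)) return(metadata(object)$truth)
  rd <- rowData(object)
  if (!"true_class" %in% colnames(rd))
    stop("no truth table attached to this experiment")
  rd
})
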