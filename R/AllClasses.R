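#' @import methods
#' @importFrom stats median quantile p.adjust pt qt cor dist hclust sd
#'   rnorm runif medpolish setNames predict
#' @importFrom utils read.delim write.table head
NULL

## Canonical factor levels used throughout
.TISSUES <- c("P", "T")
.DOSES <- c("sham", "L", "M", "H")
.TERMS <- c("(Intercept)", "CeT", "doL", "doM", "doH",
            "CeT:doL", "CeT:doM", "CeT:doH")

#' Configuration for a synthetic expression experiment
#'
#' A \code{SimConfig} bundles everything the synthetic-data generators need:
#' the tissue-by-dose design cell sizes, the planted effect classes with their
#' log2 effect sizes, the noise model, probe replication, and the planted QC
#' defects (absent features, low-correlation outlier arrays).
#'
#' @slot nFeatures number of features (genes or miRNAs) to simulate.
#' @slot groupSizes data.frame with columns \code{tissue}, \code{dose},
#'   \code{n}: number of arrays per design cell.
#' @slot effectClasses data.frame with columns \code{label}, \code{n},
#'   \code{effect}: planted effect category, member count, and log2 effect
#'   size. Labels must be known to \code{\link{plantedBetas}}.
#' @slot baselineRange length-2 numeric, log2 units; per-feature baselines are
#'   drawn uniformly from this interval.
#' @slot residualSd residual (array-level) standard deviation, log2 units.
#' @slot probesPerFeature number of replicate probes per feature.
#' @slot probeSd probe-level measurement noise SD, log2 units.
#' @slot probeAffinitySd SD of fixed per-probe affinity offsets, log2 units.
#' @slot outlierArrays number of extra arrays planted as low-correlation
#'   outliers (within-array permuted values).
#' @slot absentFraction fraction of features planted below the detection
#'   threshold ("absent").
#' @slot seed integer seed; identical configurations produce bit-identical
#'   datasets.
#' @export
setClass("SimConfig", representation(
  nFeatures = "integer",
  groupSizes = "data.frame",
  effectClasses = "data.frame",
  baselineRange = "numeric",
  residualSd = "numeric",
  probesPerFeature = "integer",
  probeSd = "numeric",
  probeAffinitySd = "numeric",
  outlierArrays = "integer",
  absentFraction = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@nFeatures) != 1L || is.na(object@nFeatures) ||
      object@nFeatures < 1L)
    msg <- c(msg, "nFeatures must be a positive integer")
  gs <- object@groupSizes
  if (!all(c("tissue", "dose", "n") %in% names(gs)))
    msg <- c(msg, "groupSizes needs columns tissue, dose, n")
  else {
    if (!all(gs$tissue %in% .TISSUES))
      msg <- c(msg, "groupSizes$tissue must be 'P' or 'T'")
    if (!all(gs$dose %in% .DOSES))
      msg <- c(msg, "groupSizes$dose must be one of sham, L, M, H")
    if (any(gs$n < 0))
      msg <- c(msg, "group sizes must be nonnegative")
  }
  ec <- object@effectClasses
  if (nrow(ec)) {
    if (!all(c("label", "n", "effect") %in% names(ec)))
      msg <- c(msg, "effectClasses needs columns label, n, effect")
    else if (sum(ec$n) > object@nFeatures)
      msg <- c(msg, "planted effect-class counts exceed nFeatures")
    if (any(ec$n < 0)) msg <- c(msg, "effect-class counts must be nonnegative")
  }
  if (length(object@baselineRange) != 2L ||
      diff(object@baselineRange) < 0)
    msg <- c(msg, "baselineRange must be an increasing length-2 numeric")
  if (!(length(object@residualSd) == 1L && object@residualSd > 0))
    msg <- c(msg, "residualSd must be > 0")
  if (object@probesPerFeature < 1L)
    msg <- c(msg, "probesPerFeature must be >= 1")
  if (object@outlierArrays < 0L)
    msg <- c(msg, "outlierArrays must be nonnegative")
  if (object@absentFraction < 0 || object@absentFraction > 1)
    msg <- c(msg, "absentFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-feature OLS fit of the tissue-by-dose interaction model
#'
#' Holds, for every feature, the estimates of the eight model coefficients
#' (intercept, tumor effect CeT, dose effects doL/doM/doH, and the
#' tissue-by-dose interactions CeT:doL, CeT:doM, CeT:doH), their standard
#' errors, t statistics, two-sided p-values, and per-term Benjamini-Hochberg
#' q-values, together with the shared design information needed to test
#' arbitrary contrasts.
#'
#' @slot coefficients,stderr,tstat,pvalue,qvalue feature-by-term matrices.
#' @slot sigma per-feature residual standard deviation.
#' @slot df residual degrees of freedom (n samples - 8).
#' @slot design the model matrix used.
#' @slot covUnscaled unscaled coefficient covariance \eqn{(X'X)^{-1}}.
#' @export
setClass("InteractionFit", representation(
  coefficients = "matrix",
  stderr = "matrix",
  tstat = "matrix",
  pvalue = "matrix",
  qvalue = "matrix",
  sigma = "numeric",
  df = "numeric",
  design = "matrix",
  covUnscaled = "matrix"
))

setValidity("InteractionFit", function(object) {
  dims <- vapply(list(object@stderr, object@tstat, object@pvalue,
                      object@qvalue),
                 function(m) identical(dim(m), dim(object@coefficients)),
                 logical(1))
  if (!all(dims)) return("coefficient-shaped slots have inconsistent dims")
  if (object@df < 1) return("residual degrees of freedom must be >= 1")
  TRUE
})

#' Present/absent detection calls
#'
#' Boolean feature-by-array detection calls; a feature is called present in an
#' array when its intensity strictly exceeds that array's detection threshold,
#' the stated percentile of the array's own intensity distribution (ties at
#' the threshold are called absent).
#'
#' @slot calls logical feature-by-array matrix (TRUE = present).
#' @slot thresholds per-array intensity threshold.
#' @slot percentile the percentile used (default 0.05).
#' @export
setClass("DetectionCalls", representation(
  calls = "matrix",
  thresholds = "numeric",
  percentile = "numeric"
))

setValidity("DetectionCalls", function(object) {
  if (!is.logical(object@calls)) return("calls must be a logical matrix")
  if (length(object@thresholds) != ncol(object@calls))
    return("one threshold per array required")
  TRUE
})

#' Array-level quality-control report
#'
#' Per-array relative log expression (RLE) summaries and/or mean between-array
#' Spearman correlations, plus the identifiers of arrays flagged for
#' exclusion.
#'
#' @slot arrays array identifiers.
#' @slot rleMedian,rleIqr per-array RLE median and IQR (NA when not computed).
#' @slot meanCor per-array mean between-array correlation (NA when not
#'   computed).
#' @slot excluded identifiers of flagged arrays.
#' @slot k the threshold multiplier used for outlier flagging.
#' @slot note diagnostic notes (e.g. too few arrays to flag outliers).
#' @export
setClass("QcReport", representation(
  arrays = "character",
  rleMedian = "numeric",
  rleIqr = "numeric",
  meanCor = "numeric",
  excluded = "character",
  k = "numeric",
  note = "character"
))

setValidity("QcReport", function(object) {
  if (!all(object@excluded %in% object@arrays))
    return("excluded arrays must be a subset of the array ids")
  TRUE
})

#' Result of the resampling signature extraction
#'
#' Output of \code{\link{genSigPred}}: the consensus gene list of the
#' requested size, per-gene selection frequencies over the R resampling
#' iterations, the per-iteration test-set misclassification rates P(N, iter),
#' and their mean, the overall prediction error Per(N).
#'
#' @slot consensus the N consensus gene identifiers (most frequently
#'   selected).
#' @slot frequency named selection frequency in [0, 1] for every gene ever
#'   selected.
#' @slot meanScore named mean absolute ranking statistic across the
#'   iterations in which each gene was selected (used to break frequency
#'   ties).
#' @slot iterError per-iteration test-set error P(N, iter).
#' @slot perN mean of iterError, the overall prediction error Per(N).
#' @slot N,R signature size and resampling count.
#' @slot iterGenes list of the R per-iteration top-N gene sets.
#' @slot degenerate logical flag per iteration (TRUE if the iteration hit a
#'   degenerate split; such iterations are still recorded).
#' @export
setClass("SignatureResult", representation(
  consensus = "character",
  frequency = "numeric",
  meanScore = "numeric",
  iterError = "numeric",
  perN = "numeric",
  N = "integer",
  R = "integer",
  iterGenes = "list",
  degenerate = "logical"
))

setValidity("SignatureResult", function(object) {
  if (any(object@frequency < 0 | object@frequency > 1))
    return("selection frequencies must lie in [0, 1]")
  if (length(object@iterError) != object@R)
    return("one recorded error per resampling iteration required")
  if (abs(object@perN - mean(object@iterError)) > 1e-12)
    return("perN must equal the mean of the per-iteration errors")
  TRUE
})

#' Subset-taxonomy assignments for interaction-significant miRNAs
#'
#' One row per miRNA whose tissue-by-dose interaction passed the FDR cutoff,
#' with the four contrast p-values (smoke effect in tumor, smoke effect in
#' parenchyma, tissue effect in sham, tissue effect under exposure), the
#' corresponding effect estimates, and the terminal category label assigned by
#' the subset tree.
#'
#' @slot table a DataFrame with the per-miRNA classification evidence.
#' @slot alpha the raw-p significance level used for the contrasts.
#' @slot fdr the interaction FDR cutoff defining the classified set.
#' @export
setClass("MirnaCategoryTable", representation(
  table = "DataFrame",
  alpha = "numeric",
  fdr = "numeric"
))

#' Two-way hierarchical clustering result
#'
#' Row and column dendrograms (as \code{hclust} objects) plus the matrix they
#' were computed on, preserving the distance metric and linkage used.
#'
#' @slot rowDendrogram,colDendrogram \code{hclust} merge trees.
#' @slot matrix the clustered matrix.
#' @slot metric distance metric ("euclidean" or "squared-euclidean").
#' @slot linkage agglomeration method.
#' @export
setClass("ClusterResult", representation(
  rowDendrogram = "ANY",
  colDendrogram = "ANY",
  matrix = "matrix",
  metric = "character",
  linkage = "character"
))

setValidity("ClusterResult", function(object) {
  ok <- function(h, n) is.null(h) ||
    (inherits(h, "hclust") && length(h$order) == n &&
       !is.unsorted(h$height))
  if (!ok(object@rowDendrogram, nrow(object@matrix)))
    return("row dendrogram inconsistent with matrix (or heights decrease)")
  if (!ok(object@colDendrogram, ncol(object@matrix)))
    return("column dendrogram inconsistent with matrix (or heights decrease)")
  TRUE
})
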