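## GenSigPred: resampling-based discriminative gene-signature extraction.
##
## Each of R iterations draws a stratified 20%/80% train/test split, ranks
## genes on the training data by the absolute SAM d-statistic, selects the
## top N, trains a linear SVM on those genes, and records the test-set
## misclassification rate P(N, iter). The consensus signature is the N genes
## most frequently selected across iterations, and Per(N) is the mean of the
## recorded errors.

#' SAM d-statistic for a two-class comparison
#'
#' The moderated mean-difference statistic
#' \eqn{d = (\bar x_1 - \bar x_2) / (s + s_0)}, where \eqn{s} is the pooled
#' two-sample standard error and the fudge constant \eqn{s_0} stabilizes
#' low-variance features. With \eqn{s_0 = 0}, \eqn{d} is the ordinary pooled
#' two-sample t statistic. By default \eqn{s_0} is the 90th percentile of the
#' per-feature \eqn{s} distribution, which keeps the statistic fully
#' deterministic.
#'
#' @param m feature-by-sample log2 matrix.
#' @param labels two-level factor (or coercible) over the samples; each
#'   class needs at least two samples. The difference is taken as
#'   first level minus second level.
#' @param s0 fudge constant; when NULL, the \code{s0Quantile} quantile of the
#'   pooled standard errors is used.
#' @param s0Quantile quantile defining the default \eqn{s_0} (default 0.9).
#' @return named numeric vector of d-scores; the pooled standard errors are
#'   attached as attribute \code{"s"} and the fudge constant as \code{"s0"}.
#' @export
samStatistic <- function(m, labels, s0 = NULL, s0Quantile = 0.9) {
  m <- as.matrix(m)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required")
  n1 <- sum(labels == levels(labels)[1L])
  n2 <- sum(labels == levels(labels)[2L])
  if (min(n1, n2) < 2L)
    stop("each class needs at least 2 samples")
  m1 <- m[, labels == levels(labels)[1L], drop = FALSE]
  m2 <- m[, labels == levels(labels)[2L], drop = FALSE]
  mean1 <- rowMeans(m1)
  mean2 <- rowMeans(m2)
  ss1 <- rowSums((m1 - mean1)^2)
  ss2 <- rowSums((m2 - mean2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  if (is.null(s0)) s0 <- quantile(s, s0Quantile, names = FALSE)
  d <- (mean1 - mean2) / (s + s0)
  structure(setNames(d, rownames(m)), s = s, s0 = s0)
}

#' Stratified train/test split
#'
#' Draws a class-stratified random split: per class \eqn{c},
#' \eqn{\lceil f \cdot n_c \rceil} samples go to training and the remainder
#' to test. The two index sets are disjoint and exhaustive.
#'
#' @param labels per-sample class labels.
#' @param trainFraction fraction f in (0, 1) assigned to training
#'   (default 0.2).
#' @param seed optional integer seed for reproducibility.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
splitTrainTest <- function(labels, trainFraction = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  labels <- factor(labels)
  train <- integer()
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    nTrain <- ceiling(trainFraction * length(idx))
    if (nTrain >= length(idx))
      stop("class '", lv, "' too small to be split at fraction ",
           trainFraction)
    train <- c(train, sort(sample(idx, nTrain)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train a linear support-vector machine on a gene subset
#'
#' Thin wrapper around \code{e1071::svm} with a linear kernel and cost 1
#' (C-classification, no rescaling), the minimal-assumption default for
#' p >> n expression data. Deterministic given the data.
#'
#' @param x training samples-by-genes matrix.
#' @param labels training class labels (two classes present).
#' @param cost SVM regularization constant (default 1).
#' @return a fitted \code{svm} object.
#' @export
trainClassifier <- function(x, labels, cost = 1) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("training set is degenerate: only one class present")
  e1071::svm(as.matrix(x), droplevels(labels), kernel = "linear",
             cost = cost, scale = FALSE, type = "C-classification")
}

#' Misclassification rate of a classifier on a test set
#'
#' @param classifier a fitted classifier supporting \code{predict}.
#' @param x test samples-by-genes matrix (nonempty).
#' @param labels true test labels.
#' @return misclassification fraction in [0, 1].
#' @export
evaluateClassifier <- function(classifier, x, labels) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty test set")
  pred <- predict(classifier, x)
  mean(as.character(pred) != as.character(labels))
}

#' Resampling consensus signature extraction (GenSigPred)
#'
#' Runs \code{R} iterations of stratified split (train fraction
#' \code{trainFraction}), SAM ranking on the training samples, top-N
#' selection, linear-SVM training and test-set error measurement, then
#' returns the N genes most frequently selected across iterations together
#' with the error curve evidence. Frequency ties at the consensus boundary
#' are broken by the genes' mean absolute d-score over the iterations that
#' selected them, then lexicographically -- so the result is deterministic
#' given the master seed, which spawns one child seed per iteration.
#'
#' @param m feature-by-sample log2 matrix (e.g. tumor samples only).
#' @param labels two-class sample labels (e.g. sham vs MS-300 tumors).
#' @param N signature size (at most the feature-pool size).
#' @param R number of resampling iterations (default 50).
#' @param trainFraction training fraction per class (default 0.2).
#' @param seed master seed (default 1).
#' @param featurePool optional character vector restricting the ranking to a
#'   pre-selected pool (e.g. interaction-significant genes); by default all
#'   features compete, so ranking happens entirely inside each training
#'   split.
#' @param cost SVM cost passed to \code{\link{trainClassifier}}.
#' @return a \code{\linkS4class{SignatureResult}}.
#' @export
genSigPred <- function(m, labels, N, R = 50L, trainFraction = 0.2,
                       seed = 1L, featurePool = NULL, cost = 1) {
  m <- as.matrix(m)
  if (!is.null(featurePool)) {
    missing <- setdiff(featurePool, rownames(m))
    if (length(missing))
      stop("featurePool genes absent from the matrix: ",
           paste(head(missing, 5L), collapse = ", "))
    m <- m[featurePool, , drop = FALSE]
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  N <- as.integer(N)
  R <- as.integer(R)
  if (N < 1L || N > nrow(m)) stop("N must lie in [1, feature pool size]")
  if (R < 1L) stop("R must be >= 1")

  set.seed(seed)
  childSeeds <- sample.int(.Machine$integer.max, R)
  genes <- rownames(m)
  count <- setNames(numeric(nrow(m)), genes)
  scoreSum <- setNames(numeric(nrow(m)), genes)
  iterError <- numeric(R)
  iterGenes <- vector("list", R)
  degenerate <- logical(R)

  for (it in seq_len(R)) {
    set.seed(childSeeds[it])
    sp <- splitTrainTest(labels, trainFraction)
    d <- samStatistic(m[, sp$train, drop = FALSE], labels[sp$train])
    ord <- order(-abs(d), genes)
    top <- genes[ord[seq_len(N)]]
    iterGenes[[it]] <- top
    count[top] <- count[top] + 1
    scoreSum[top] <- scoreSum[top] + abs(d[top])
    fit <- trainClassifier(t(m[top, sp$train, drop = FALSE]),
                           labels[sp$train], cost = cost)
    iterError[it] <- evaluateClassifier(
      fit, t(m[top, sp$test, drop = FALSE]), labels[sp$test])
  }

  selected <- count > 0
  freq <- count[selected] / R
  meanScore <- scoreSum[selected] / count[selected]
  ord <- order(-freq, -meanScore, names(freq))
  consensus <- names(freq)[ord][seq_len(min(N, sum(selected)))]
  new("SignatureResult",
      consensus = consensus,
      frequency = freq,
      meanScore = meanScore,
      iterError = iterError,
      perN = mean(iterError),
      N = N, R = R,
      iterGenes = iterGenes,
      degenerate = degenerate)
}

#' Choose the signature size from an error curve
#'
#' Runs \code{\link{genSigPred}} for every candidate N with the same master
#' seed (so all candidates see identical splits) and returns the N with the
#' smallest overall prediction error Per(N); ties go to the smallest N.
#'
#' @param m,labels,R,trainFraction,seed,featurePool,cost as in
#'   \code{\link{genSigPred}}.
#' @param candidates integer vector of signature sizes to try.
#' @return list with \code{N} (the chosen size), \code{perCurve} (named
#'   Per(N) values over the candidates) and \code{results} (the per-N
#'   \code{\linkS4class{SignatureResult}} objects).
#' @export
selectSignatureSize <- function(m, labels, candidates, R = 50L,
                                trainFraction = 0.2, seed = 1L,
                                featurePool = NULL, cost = 1) {
  candidates <- as.integer(candidates)
  if (!length(candidates)) stop("at least one candidate N is required")
  results <- lapply(candidates, function(N)
    genSigPred(m, labels, N = N, R = R, trainFraction = trainFraction,
               seed = seed, featurePool = featurePool, cost = cost))
  per <- vapply(results, perError, numeric(1))
  names(per) <- as.character(candidates)
  best <- candidates[order(per, candidates)][1L]
  list(N = best, perCurve = per,
       results = setNames(results, as.character(candidates)))
}

#' @describeIn accessors the consensus gene list of a signature result.
#' @export
setMethod("consensusGenes", "SignatureResult",
          function(object, ...) object@consensus)

#' @describeIn accessors per-gene selection frequencies over the R
#'   iterations.
#' @export
setMethod("selectionFrequency", "SignatureResult",
          function(object, ...) object@frequency)

#' @describeIn accessors the overall prediction error Per(N).
#' @export
setMethod("perError", "SignatureResult", function(object, ...) object@perN)

#' @describeIn accessors the per-iteration test errors P(N, iter).
#' @export
setMethod("iterationErrors", "SignatureResult",
          function(object, ...) object@iterError)

setMethod("show", "SignatureResult", function(object) {
  cat("SignatureResult: N =", object@N, ", R =", object@R, "\n")
  cat("  Per(N) =", round(object@perN, 4), "\n")
  cat("  consensus head:",
      paste(head(object@consensus, 5L), collapse = ", "), "...\n")
})
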