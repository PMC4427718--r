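## The 8-term tissue-by-dose interaction model
##
##   y = b0 + b1*CeT + b2*doL + b3*doM + b4*doH
##          + b5*CeT:doL + b6*CeT:doM + b7*CeT:doH + e
##
## CeT indicates tumor tissue, doL/doM/doH the three smoke-concentration
## groups; the interaction CeT:doH is the difference-in-differences between
## the tumor-vs-parenchyma contrast under MS-300 exposure and under sham.
## The design is saturated in the eight tissue:dose cells, so fitted cell
## means equal observed cell means and b7 equals
## (mean T_H - mean P_H) - (mean T_sham - mean P_sham) for any data.

#' Build the tissue-by-dose interaction design matrix
#'
#' Produces the fixed-order 8-column 0/1 design: intercept, tumor indicator
#' \code{CeT}, dose indicators \code{doL}, \code{doM}, \code{doH} (sham is
#' the reference), and the three products \code{CeT:doL}, \code{CeT:doM},
#' \code{CeT:doH}. A sham-parenchyma sample codes as (1,0,0,0,0,0,0,0).
#'
#' @param sheet a sample sheet (data.frame or DataFrame) with columns
#'   \code{tissue} in \{T, P\} and \code{dose} in \{sham, L, M, H\}.
#' @return numeric samples-by-8 matrix; full column rank whenever every
#'   tissue-by-dose cell is populated.
#' @export
buildDesignMatrix <- function(sheet) {
  sheet <- as.data.frame(sheet)
  stopifnot(all(c("tissue", "dose") %in% names(sheet)))
  badT <- !(sheet$tissue %in% .TISSUES)
  badD <- !(sheet$dose %in% .DOSES)
  if (any(badT | badD)) {
    who <- if (!is.null(sheet$sample_id)) sheet$sample_id else
      rownames(sheet)
    stop("unknown tissue/dose level for sample(s): ",
         paste(who[badT | badD], collapse = ", "))
  }
  ceT <- as.numeric(sheet$tissue == "T")
  doL <- as.numeric(sheet$dose == "L")
  doM <- as.numeric(sheet$dose == "M")
  doH <- as.numeric(sheet$dose == "H")
  X <- cbind(1, ceT, doL, doM, doH, ceT * doL, ceT * doM, ceT * doH)
  dimnames(X) <- list(
    if (!is.null(sheet$sample_id)) sheet$sample_id else rownames(sheet),
    .TERMS)
  X
}

#' Fit the interaction model to every feature by ordinary least squares
#'
#' One OLS fit per feature against the shared design, vectorized through a
#' single QR decomposition. Returns coefficient estimates, standard errors,
#' t statistics, two-sided p-values with \code{n - 8} residual degrees of
#' freedom, and per-term Benjamini-Hochberg q-values computed across
#' features. No variance moderation is applied: each feature uses its own
#' residual variance, and all samples are treated as independent.
#'
#' @param object a log2 feature-by-sample matrix, or a
#'   \code{SummarizedExperiment} whose \code{colData} carries
#'   \code{tissue}/\code{dose}.
#' @param design the design matrix from \code{\link{buildDesignMatrix}};
#'   built from \code{colData} when \code{object} is a
#'   SummarizedExperiment and \code{design} is missing.
#' @param assay assay name used when \code{object} is a
#'   SummarizedExperiment (default \code{"exprs"}).
#' @return an \code{\linkS4class{InteractionFit}}.
#' @export
fitInteractionModel <- function(object, design = NULL, assay = "exprs") {
  if (is(object, "SummarizedExperiment")) {
    if (is.null(design))
      design <- buildDesignMatrix(sampleSheet(object))
    m <- SummarizedExperiment::assay(object, assay)
  } else {
    m <- as.matrix(object)
    if (is.null(design)) stop("a design matrix is required")
  }
  if (ncol(m) != nrow(design))
    stop("columns of the matrix must align with rows of the design")
  n <- nrow(design)
  p <- ncol(design)
  if (n <= p)
    stop("need more samples (", n, ") than model terms (", p, ")")
  qrX <- qr(design)
  if (qrX$rank < p) {
    cells <- table(factor(design[, "CeT"], levels = 0:1),
                   apply(design[, 3:5, drop = FALSE], 1, paste,
                         collapse = ""))
    stop("design matrix is rank deficient (", qrX$rank, " < ", p,
         "); check that every tissue:dose cell is populated")
  }
  coefs <- t(qr.coef(qrX, t(m)))                     # features x 8
  fitted <- coefs %*% t(design)
  res <- m - fitted
  df <- n - p
  sigma2 <- rowSums(res^2) / df
  covU <- chol2inv(qr.R(qrX))                        # (X'X)^{-1}
  dimnames(covU) <- list(colnames(design), colnames(design))
  se <- sqrt(sigma2 %o% diag(covU))
  tstat <- coefs / se
  pval <- 2 * pt(-abs(tstat), df)
  qval <- apply(pval, 2L, p.adjust, method = "BH")
  dn <- list(rownames(m), colnames(design))
  dimnames(coefs) <- dimnames(se) <- dimnames(tstat) <-
    dimnames(pval) <- dn
  dimnames(qval) <- dn
  new("InteractionFit",
      coefficients = coefs, stderr = se, tstat = tstat,
      pvalue = pval, qvalue = qval,
      sigma = sqrt(sigma2), df = df, design = design, covUnscaled = covU)
}

#' Model term names
#' @return the eight coefficient names in design-column order.
#' @export
modelTerms <- function() .TERMS

#' Two-sided t-test p-values for one model term
#'
#' @param fit an \code{\linkS4class{InteractionFit}}.
#' @param term one of \code{\link{modelTerms}}.
#' @return named p-value vector over features.
#' @export
testTerm <- function(fit, term) {
  stopifnot(is(fit, "InteractionFit"))
  if (!term %in% colnames(fit@pvalue))
    stop("unknown model term: ", term)
  fit@pvalue[, term]
}

#' Test a linear contrast of the model coefficients
#'
#' Wald t-test of \eqn{w'\beta} per feature, with standard error
#' \eqn{\hat\sigma \sqrt{w'(X'X)^{-1}w}} and the fit's residual degrees of
#' freedom.
#'
#' @param fit an \code{\linkS4class{InteractionFit}}.
#' @param weights numeric length-8 contrast weights (at least one nonzero),
#'   in \code{\link{modelTerms}} order.
#' @return data.frame with per-feature \code{estimate}, \code{se}, \code{t}
#'   and two-sided \code{p}.
#' @export
testContrast <- function(fit, weights) {
  stopifnot(is(fit, "InteractionFit"))
  weights <- as.numeric(weights)
  if (length(weights) != ncol(fit@coefficients))
    stop("contrast weights must have length ", ncol(fit@coefficients))
  if (all(weights == 0)) stop("contrast weights are all zero")
  est <- drop(fit@coefficients %*% weights)
  se <- fit@sigma * sqrt(drop(crossprod(weights,
                                        fit@covUnscaled %*% weights)))
  t <- est / se
  data.frame(estimate = est, se = se, t = t,
             p = 2 * pt(-abs(t), fit@df),
             row.names = rownames(fit@coefficients))
}

#' The four subset-taxonomy contrasts
#'
#' Weight vectors (in \code{\link{modelTerms}} order) for the pairwise
#' comparisons that drive the miRNA subset tree: the smoke (MS-300 vs sham)
#' effect within tumor and within parenchyma, and the tumor-vs-parenchyma
#' tissue effect within sham and within MS-300.
#'
#' @return named list of four length-8 weight vectors.
#' @export
msContrasts <- function() {
  w <- function(...) {
    v <- setNames(numeric(8L), .TERMS)
    v[c(...)] <- 1
    v
  }
  list(
    msInTumor = w("doH", "CeT:doH"),
    msInParenchyma = w("doH"),
    tissueInSham = w("CeT"),
    tissueInMs = w("CeT", "CeT:doH")
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; thresholding the returned q-values at \eqn{\alpha}
#' reproduces the BH rejection set at level \eqn{\alpha}.
#'
#' @param p raw p-values in [0, 1].
#' @return q-value vector of the same length.
#' @export
adjustFdr <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Extract estimated coefficients
#' @param object an \code{\linkS4class{InteractionFit}}.
#' @return features-by-8 coefficient matrix.
#' @export
setMethod("coef", "InteractionFit", function(object) object@coefficients)

#' Per-term FDR q-values of a fit
#' @param fit an \code{\linkS4class{InteractionFit}}.
#' @param term optional term name; all terms when missing.
#' @return q-value matrix or vector.
#' @export
qvalues <- function(fit, term = NULL) {
  stopifnot(is(fit, "InteractionFit"))
  if (is.null(term)) return(fit@qvalue)
  if (!term %in% colnames(fit@qvalue)) stop("unknown model term: ", term)
  fit@qvalue[, term]
}

#' Residual degrees of freedom of a fit
#' @param fit an \code{\linkS4class{InteractionFit}}.
#' @return scalar degrees of freedom (n samples minus 8).
#' @export
residualDf <- function(fit) {
  stopifnot(is(fit, "InteractionFit"))
  fit@df
}

setMethod("show", "InteractionFit", function(object) {
  cat("InteractionFit:", nrow(object@coefficients), "features,",
      nrow(object@design), "samples, residual df", object@df, "\n")
  cat("  terms:", paste(colnames(object@coefficients), collapse = ", "),
      "\n")
  q7 <- object@qvalue[, "CeT:doH"]
  cat("  CeT:doH q<0.05:", sum(q7 < 0.05),
      " q<0.01:", sum(q7 < 0.01), "\n")
})
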