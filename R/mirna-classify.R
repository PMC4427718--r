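## Subset-tree classification of interaction-significant miRNAs.
##
## Features whose tissue-by-dose interaction (CeT:doH) passes the FDR cutoff
## are routed through a three-level tree driven by four model contrasts at
## raw p < alpha:
##   Level 1 (where is the smoke effect?): parenchyma only / tumor only /
##     both tissues (both splits by smoke-effect sign concordance).
##   Level 2 (parenchyma-only branch; tumor-vs-parenchyma tissue effect):
##     exposure-effect-only (no tissue effect in sham), tissue effect that
##     vanishes under exposure, or tissue effect in both conditions.
##   Level 3 (tissue effect in both): sign pattern of the sham and exposed
##     tissue effects -- tumor-high (+,+), tumor-low (-,-), or mixed.

#' Classify interaction-significant miRNAs into the subset taxonomy
#'
#' Selects features with interaction FDR q-value below \code{fdr} (default
#' 0.05), computes the four taxonomy contrasts
#' (\code{\link{msContrasts}}), and assigns each feature a terminal category
#' by the tree above, using raw contrast p-values at level \code{alpha}.
#' Features whose two smoke-effect contrasts are both non-significant are
#' labelled \code{"unclassified"}.
#'
#' @param fit an \code{\linkS4class{InteractionFit}}.
#' @param alpha raw-p significance level for the contrasts (default 0.05).
#' @param fdr FDR cutoff on the CeT:doH q-values defining the classified set
#'   (default 0.05).
#' @return a \code{\linkS4class{MirnaCategoryTable}}.
#' @export
classifyInteractionMirnas <- function(fit, alpha = 0.05, fdr = 0.05) {
  stopifnot(is(fit, "InteractionFit"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  q7 <- qvalues(fit, "CeT:doH")
  sel <- which(q7 < fdr)
  cw <- msContrasts()
  ct <- lapply(cw, function(w) testContrast(fit, w))

  n <- length(sel)
  level1 <- character(n)
  terminal <- character(n)
  for (k in seq_len(n)) {
    i <- sel[k]
    pMsT <- ct$msInTumor$p[i]
    pMsP <- ct$msInParenchyma$p[i]
    pTiS <- ct$tissueInSham$p[i]
    pTiM <- ct$tissueInMs$p[i]
    eMsT <- ct$msInTumor$estimate[i]
    eMsP <- ct$msInParenchyma$estimate[i]
    eTiS <- ct$tissueInSham$estimate[i]
    eTiM <- ct$tissueInMs$estimate[i]
    if (pMsP < alpha && pMsT >= alpha) {
      level1[k] <- "parenchyma-only"
      if (pTiS >= alpha) {
        terminal[k] <- "parenchyma-only/exposure-effect-only"
      } else if (pTiM >= alpha) {
        terminal[k] <- "parenchyma-only/tissue-effect-vanishes"
      } else if (eTiS > 0 && eTiM > 0) {
        terminal[k] <- "parenchyma-only/tumor-high"
      } else if (eTiS < 0 && eTiM < 0) {
        terminal[k] <- "parenchyma-only/tumor-low"
      } else {
        terminal[k] <- "parenchyma-only/mixed"
      }
    } else if (pMsT < alpha && pMsP >= alpha) {
      level1[k] <- "tumor-only"
      terminal[k] <- "tumor-only"
    } else if (pMsT < alpha && pMsP < alpha) {
      level1[k] <- "both"
      terminal[k] <- if (sign(eMsT) == sign(eMsP))
        "both/concordant" else "both/discordant"
    } else {
      level1[k] <- "unclassified"
      terminal[k] <- "unclassified"
    }
  }

  ids <- rownames(fit@coefficients)[sel]
  tab <- DataFrame(
    feature_id = ids,
    interaction_q = q7[sel],
    p_ms_tumor = ct$msInTumor$p[sel],
    p_ms_parenchyma = ct$msInParenchyma$p[sel],
    p_tissue_sham = ct$tissueInSham$p[sel],
    p_tissue_ms = ct$tissueInMs$p[sel],
    est_ms_tumor = ct$msInTumor$estimate[sel],
    est_ms_parenchyma = ct$msInParenchyma$estimate[sel],
    est_tissue_sham = ct$tissueInSham$estimate[sel],
    est_tissue_ms = ct$tissueInMs$estimate[sel],
    level1 = level1,
    category = terminal,
    row.names = ids
  )
  new("MirnaCategoryTable", table = tab, alpha = alpha, fdr = fdr)
}

#' @describeIn accessors the per-miRNA classification table.
#' @export
setMethod("categoryTable", "MirnaCategoryTable",
          function(object, ...) object@table)

#' @rdname categoryCounts
#' @export
setMethod("categoryCounts", "MirnaCategoryTable",
          function(object, level = c("terminal", "level1")) {
  level <- match.arg(level)
  labels <- if (level == "terminal")
    c(.FIG8_LABELS, "unclassified")
  else c("parenchyma-only", "tumor-only", "both", "unclassified")
  col <- if (level == "terminal") "category" else "level1"
  tab <- table(factor(object@table[[col]], levels = labels))
  out <- as.integer(tab)
  names(out) <- labels
  out
})

setMethod("show", "MirnaCategoryTable", function(object) {
  cat("MirnaCategoryTable:", nrow(object@table),
      "interaction-significant miRNAs (FDR <", object@fdr,
      "), contrasts at raw p <", object@alpha, "\n")
  cc <- categoryCounts(object, "level1")
  cat(" ", paste(names(cc), cc, sep = ": ", collapse = "; "), "\n")
})
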