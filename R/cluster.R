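## Clustering and heatmap conventions used in the study's figures: rows
## centered by their mean across tumor samples, two-way agglomerative
## clustering with complete linkage under Euclidean or squared-Euclidean
## distance, and a symmetric red/blue color scale about zero.

#' Center rows by their mean across tumor samples
#'
#' Subtracts from every row its mean over tumor-labelled columns, so tumor
#' columns average zero per feature. Idempotent.
#'
#' @param m feature-by-sample matrix.
#' @param sheet sample sheet with a \code{tissue} column aligned to the
#'   columns of \code{m}; at least one tumor (T) sample required.
#' @return centered matrix.
#' @export
centerRowsByTumorMean <- function(m, sheet) {
  m <- as.matrix(m)
  sheet <- as.data.frame(sheet)
  tumor <- sheet$tissue == "T"
  if (!any(tumor)) stop("no tumor samples to center on")
  m - rowMeans(m[, tumor, drop = FALSE])
}

#' Two-way hierarchical clustering
#'
#' Complete-linkage agglomerative clustering of rows and (optionally)
#' columns under Euclidean or squared-Euclidean distance, via
#' \code{stats::hclust}. Squaring the distances is a monotone transform, so
#' both metrics give the same tree topology whenever pairwise distances are
#' distinct; merge heights differ.
#'
#' @param m numeric matrix (no missing/NaN values).
#' @param metric \code{"euclidean"} or \code{"squared-euclidean"}.
#' @param linkage agglomeration method (default \code{"complete"}).
#' @param clusterColumns also cluster columns (default TRUE).
#' @return a \code{\linkS4class{ClusterResult}}.
#' @export
hierarchicalCluster <- function(m,
                                metric = c("euclidean",
                                           "squared-euclidean"),
                                linkage = "complete",
                                clusterColumns = TRUE) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("matrix contains missing or non-finite values")
  metric <- match.arg(metric)
  mkDist <- function(x) {
    d <- dist(x, method = "euclidean")
    if (metric == "squared-euclidean") d <- d^2
    d
  }
  if (nrow(m) < 2L) stop("at least two rows are required")
  rowH <- hclust(mkDist(m), method = linkage)
  colH <- if (clusterColumns && ncol(m) >= 2L)
    hclust(mkDist(t(m)), method = linkage) else NULL
  new("ClusterResult", rowDendrogram = rowH, colDendrogram = colH,
      matrix = m, metric = metric, linkage = linkage)
}

#' @describeIn accessors row and column leaf orders of a clustering result,
#'   as a list of identifier vectors.
#' @export
setMethod("leafOrder", "ClusterResult", function(object, ...) {
  rn <- rownames(object@matrix)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(object@matrix)))
  cn <- colnames(object@matrix)
  if (is.null(cn)) cn <- as.character(seq_len(ncol(object@matrix)))
  list(rows = rn[object@rowDendrogram$order],
       columns = if (is.null(object@colDendrogram)) cn
       else cn[object@colDendrogram$order])
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", nrow(object@matrix), "x", ncol(object@matrix),
      "matrix;", object@metric, "distance,", object@linkage,
      "linkage\n")
})

#' Render a clustered heatmap and the leaf-ordered matrix
#'
#' Writes a heatmap image (via \pkg{pheatmap}, using the precomputed
#' dendrograms and a color scale symmetric about zero, matching the
#' red/blue convention for tumor-mean-centered data) and a tab-delimited
#' copy of the matrix in dendrogram leaf order.
#'
#' @param cluster a \code{\linkS4class{ClusterResult}}.
#' @param file image output path (extension selects the device, e.g.
#'   \code{.png} or \code{.pdf}).
#' @param annotations optional data.frame of per-sample annotations
#'   (rownames = column ids of the matrix).
#' @param tsvFile path of the ordered-matrix TSV; defaults to \code{file}
#'   with its extension replaced by \code{.tsv}.
#' @return invisibly, a list with the \code{image} and \code{tsv} paths.
#' @export
renderHeatmap <- function(cluster, file, annotations = NULL,
                          tsvFile = NULL) {
  stopifnot(is(cluster, "ClusterResult"))
  if (is.null(tsvFile)) tsvFile <- sub("\\.[^.]+$", ".tsv", file)
  m <- cluster@matrix
  lim <- max(abs(m))
  breaks <- seq(-lim, lim, length.out = 101L)
  pheatmap::pheatmap(
    m,
    cluster_rows = cluster@rowDendrogram,
    cluster_cols = if (is.null(cluster@colDendrogram)) FALSE
    else cluster@colDendrogram,
    breaks = breaks,
    annotation_col = annotations,
    show_rownames = nrow(m) <= 60L,
    filename = file,
    silent = TRUE
  )
  ord <- leafOrder(cluster)
  writeExpressionTsv(m[ord$rows, ord$columns, drop = FALSE], tsvFile)
  invisible(list(image = file, tsv = tsvFile))
}
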