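#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData
NULL

#' Accessors for smokeSig result objects
#'
#' Small accessor generics following the usual Bioconductor idiom: use these
#' instead of reaching into slots.
#'
#' @param object a smokeSig S4 object.
#' @param ... passed to methods.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(object, ...) standardGeneric("sampleSheet"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(object, ...) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("detectionMatrix",
           function(object, ...) standardGeneric("detectionMatrix"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object, ...) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("excludedArrays",
           function(object, ...) standardGeneric("excludedArrays"))

#' @rdname accessors
#' @export
setGeneric("qcTable", function(object, ...) standardGeneric("qcTable"))

#' @rdname accessors
#' @export
setGeneric("consensusGenes",
           function(object, ...) standardGeneric("consensusGenes"))

#' @rdname accessors
#' @export
setGeneric("selectionFrequency",
           function(object, ...) standardGeneric("selectionFrequency"))

#' @rdname accessors
#' @export
setGeneric("perError", function(object, ...) standardGeneric("perError"))

#' @rdname accessors
#' @export
setGeneric("iterationErrors",
           function(object, ...) standardGeneric("iterationErrors"))

#' @rdname accessors
#' @export
setGeneric("categoryTable",
           function(object, ...) standardGeneric("categoryTable"))

#' Count classified miRNAs per taxonomy label
#'
#' @param object a \code{\linkS4class{MirnaCategoryTable}}.
#' @param level \code{"terminal"} for the full terminal taxonomy or
#'   \code{"level1"} for the three top-level branches (plus "unclassified").
#' @return named integer vector of counts; over either level the counts
#'   partition the classified set.
#' @export
setGeneric("categoryCounts",
           function(object, level = c("terminal", "level1"))
             standardGeneric("categoryCounts"))

#' @rdname accessors
#' @export
setGeneric("leafOrder", function(object, ...) standardGeneric("leafOrder"))
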