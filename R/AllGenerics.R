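#' @rdname ScMatrix-class
#' @param object,x an object.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ScMatrix-class
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' @rdname ScMatrix-class
#' @export
setGeneric("cellNames", function(object) standardGeneric("cellNames"))

#' @rdname BulkVector-class
#' @param object an object.
#' @export
setGeneric("bulkValues", function(object) standardGeneric("bulkValues"))

#' @rdname ImputeResult-class
#' @param object an object.
#' @export
setGeneric("imputedMatrix", function(object) standardGeneric("imputedMatrix"))

#' @rdname ImputeResult-class
#' @export
setGeneric("admmState", function(object) standardGeneric("admmState"))

#' @rdname SimTruth-class
#' @param object an object.
#' @export
setGeneric("truthMatrix", function(object) standardGeneric("truthMatrix"))

#' @rdname SimTruth-class
#' @export
setGeneric("dropoutMatrix", function(object) standardGeneric("dropoutMatrix"))

#' @rdname SimTruth-class
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname SimTruth-class
#' @export
setGeneric("bulkVector", function(object) standardGeneric("bulkVector"))

#' @rdname SimTruth-class
#' @export
setGeneric("droppedMask", function(object) standardGeneric("droppedMask"))
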