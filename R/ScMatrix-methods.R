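#' Construct a single-cell expression matrix
#'
#' Builds an [ScMatrix] from a numeric matrix in cells x genes
#' orientation. Gene and cell names default to the matrix dimnames, or
#' to `gene1..geneM` / `cell1..cellN` when absent.
#'
#' @param values numeric matrix, n cells x m genes, non-negative.
#' @param geneNames,cellNames optional character vectors of identifiers.
#'
#' @return An [ScMatrix].
#' @examples
#' x <- ScMatrix(matrix(c(1, 0, 2, 3, 0, 4), nrow = 2))
#' dim(x)
#' @export
ScMatrix <- function(values, geneNames = NULL, cellNames = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(geneNames))
        geneNames <- colnames(values) %||% paste0("gene", seq_len(ncol(values)))
    if (is.null(cellNames))
        cellNames <- rownames(values) %||% paste0("cell", seq_len(nrow(values)))
    dimnames(values) <- list(cellNames, geneNames)
    new("ScMatrix", values = values,
        geneNames = as.character(geneNames),
        cellNames = as.character(cellNames))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname ScMatrix-class
#' @export
setMethod("exprValues", "ScMatrix", function(object) object@values)

#' @rdname ScMatrix-class
#' @export
setMethod("geneNames", "ScMatrix", function(object) object@geneNames)

#' @rdname ScMatrix-class
#' @export
setMethod("cellNames", "ScMatrix", function(object) object@cellNames)

#' @rdname ScMatrix-class
#' @export
setMethod("dim", "ScMatrix", function(x) dim(x@values))

#' @rdname ScMatrix-class
#' @export
setMethod("show", "ScMatrix", function(object) {
    v <- object@values
    cat(sprintf("ScMatrix: %d cells x %d genes\n", nrow(v), ncol(v)))
    cat(sprintf("  zero fraction: %.3f\n", mean(v == 0)))
    cat(sprintf("  genes: %s...\n",
                paste(head(object@geneNames, 4L), collapse = ", ")))
    cat(sprintf("  cells: %s...\n",
                paste(head(object@cellNames, 4L), collapse = ", ")))
})

setAs("ScMatrix", "matrix", function(from) from@values)

#' Construct a bulk expression vector
#'
#' @param values non-negative numeric vector of per-gene bulk averages.
#' @param geneNames gene identifiers; default the names of `values`.
#'
#' @return A [BulkVector].
#' @examples
#' BulkVector(c(g1 = 2.5, g2 = 0.1))
#' @export
BulkVector <- function(values, geneNames = NULL) {
    if (is.null(geneNames))
        geneNames <- names(values) %||% paste0("gene", seq_along(values))
    new("BulkVector", values = as.numeric(values),
        geneNames = as.character(geneNames))
}

#' @rdname BulkVector-class
#' @export
setMethod("bulkValues", "BulkVector", function(object)
    setNames(object@values, object@geneNames))

#' @rdname BulkVector-class
#' @export
setMethod("geneNames", "BulkVector", function(object) object@geneNames)

#' @rdname BulkVector-class
#' @export
setMethod("length", "BulkVector", function(x) length(x@values))

#' @rdname BulkVector-class
#' @export
setMethod("show", "BulkVector", function(object) {
    cat(sprintf("BulkVector over %d genes (mean %.3g)\n",
                length(object@values), mean(object@values)))
})

#' @rdname ImputeResult-class
#' @export
setMethod("imputedMatrix", "ImputeResult", function(object) object@imputed)

#' @rdname ImputeResult-class
#' @export
setMethod("admmState", "ImputeResult", function(object) object@state)

#' @rdname ImputeResult-class
#' @export
setMethod("show", "ImputeResult", function(object) {
    st <- object@state
    cat(sprintf("ImputeResult: %d cells x %d genes\n",
                nrow(st@X), ncol(st@X)))
    cat(sprintf("  ADMM iterations: %d (%s)\n", st@k,
                if (st@converged) "converged" else "max iterations reached"))
    cat(sprintf("  final primal residual: %.3g\n",
                st@primalResiduals[st@k]))
    cat(sprintf("  final objective: %.6g\n", st@objectiveTrace[st@k]))
})

#' @rdname AdmmState-class
#' @export
setMethod("show", "AdmmState", function(object) {
    cat(sprintf("AdmmState after %d iterations (converged: %s)\n",
                object@k, object@converged))
})

#' @rdname SimTruth-class
#' @export
setMethod("truthMatrix", "SimTruth", function(object) object@truth)

#' @rdname SimTruth-class
#' @export
setMethod("dropoutMatrix", "SimTruth", function(object) object@dropout)

#' @rdname SimTruth-class
#' @export
setMethod("clusterLabels", "SimTruth", function(object) object@labels)

#' @rdname SimTruth-class
#' @export
setMethod("droppedMask", "SimTruth", function(object) object@maskDropped)

#' @rdname SimTruth-class
#' @export
setMethod("bulkVector", "SimTruth", function(object)
    BulkVector(object@bulk, colnames(object@truth)))

#' @rdname SimTruth-class
#' @export
setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d cells x %d genes, %d clusters\n",
                nrow(object@truth), ncol(object@truth),
                object@config@nClusters))
    cat(sprintf("  zero fraction truth/dropout: %.3f / %.3f\n",
                mean(object@truth == 0), mean(object@dropout == 0)))
    cat(sprintf("  lambda: %.4g\n", object@config@lambdaDropout))
})

#' Construct a pathway gene set
#'
#' @param name pathway name.
#' @param genes character vector of gene identifiers (at least 2).
#' @param description optional free-text description.
#'
#' @return A [PathwaySet].
#' @examples
#' pathwaySet("cellcycle", c("g1", "g2", "g7"))
#' @export
pathwaySet <- function(name, genes, description = "") {
    new("PathwaySet", name = as.character(name),
        description = as.character(description),
        genes = as.character(genes))
}

#' @rdname PathwaySet-class
#' @export
setMethod("show", "PathwaySet", function(object) {
    cat(sprintf("PathwaySet '%s': %d genes\n", object@name,
                length(object@genes)))
})
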