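#' @import methods
#' @importFrom stats cor dist ks.test median qnorm rbinom rlnorm rnorm runif sd var setNames
#' @importFrom utils read.table write.table head
#' @useDynLib scBulkImpute, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.sbiStop <- function(class, msg, ...) {
    cond <- structure(
        class = c(class, "sbiError", "error", "condition"),
        list(message = msg, call = sys.call(-1), ...)
    )
    stop(cond)
}

#' Single-cell expression matrix
#'
#' Container for a non-negative single-cell expression matrix in the
#' package's internal orientation: cells as rows, genes as columns. The
#' zero pattern of the matrix defines the observed-entry set used by the
#' imputation model: an entry is treated as observed exactly when it is
#' non-zero, and zero entries are dropout candidates.
#'
#' @slot values numeric matrix, n cells x m genes, all entries finite and
#'   non-negative.
#' @slot geneNames character vector of m unique gene identifiers.
#' @slot cellNames character vector of n unique cell identifiers.
#'
#' @seealso [ScMatrix()] for the constructor, [imputeDropouts()].
#' @name ScMatrix-class
#' @rdname ScMatrix-class
#' @exportClass ScMatrix
setClass("ScMatrix",
    representation(values = "matrix",
                   geneNames = "character",
                   cellNames = "character"))

setValidity("ScMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (nrow(v) < 2L || ncol(v) < 2L)
        return("need at least 2 cells and 2 genes")
    if (any(!is.finite(v)))
        return("'values' contains non-finite entries")
    if (any(v < 0))
        return("'values' contains negative entries")
    if (length(object@geneNames) != ncol(v))
        return("length of 'geneNames' must equal the number of gene columns")
    if (length(object@cellNames) != nrow(v))
        return("length of 'cellNames' must equal the number of cell rows")
    if (anyDuplicated(object@geneNames))
        return("duplicate gene names")
    if (anyDuplicated(object@cellNames))
        return("duplicate cell names")
    TRUE
})

#' Bulk expression vector
#'
#' Per-gene average expression from matched bulk RNA-seq, on the same
#' scale and in the same gene order as the paired [ScMatrix].
#'
#' @slot values non-negative numeric vector of length m.
#' @slot geneNames character vector of m unique gene identifiers aligned
#'   to the columns of the paired single-cell matrix.
#'
#' @seealso [BulkVector()], [alignBulk()].
#' @name BulkVector-class
#' @rdname BulkVector-class
#' @exportClass BulkVector
setClass("BulkVector",
    representation(values = "numeric", geneNames = "character"))

setValidity("BulkVector", function(object) {
    if (length(object@values) != length(object@geneNames))
        return("'values' and 'geneNames' lengths differ")
    if (any(!is.finite(object@values)))
        return("'values' contains non-finite entries")
    if (any(object@values < 0))
        return("'values' contains negative entries")
    if (anyDuplicated(object@geneNames))
        return("duplicate gene names")
    TRUE
})

#' Imputation model and solver parameters
#'
#' Weights of the convex imputation objective and controls of the ADMM
#' solver. `alpha` weights the nuclear norm (low-rank pressure across
#' cell states), `beta` weights agreement between the cell-averaged
#' imputed matrix and the bulk vector, and `gamma` is the ADMM penalty
#' (it changes the optimisation path, not the optimum).
#'
#' @slot alpha non-negative nuclear-norm weight.
#' @slot beta non-negative bulk-consistency weight.
#' @slot gamma positive ADMM penalty.
#' @slot maxIter maximum number of ADMM iterations.
#' @slot tol relative convergence tolerance (primal residual and
#'   objective change).
#' @slot innerMaxIter maximum Gauss-Seidel sweeps per X-update.
#' @slot innerTol relative convergence tolerance of the inner sweeps.
#'
#' @seealso [imputeParams()], [suggestParams()].
#' @name ImputeParams-class
#' @rdname ImputeParams-class
#' @exportClass ImputeParams
setClass("ImputeParams",
    representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                   maxIter = "integer", tol = "numeric",
                   innerMaxIter = "integer", innerTol = "numeric"))

setValidity("ImputeParams", function(object) {
    for (s in c("alpha", "beta", "gamma", "tol", "innerTol"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            return(sprintf("'%s' must be a single finite number", s))
    if (object@alpha < 0) return("'alpha' must be >= 0")
    if (object@beta < 0) return("'beta' must be >= 0")
    if (object@gamma <= 0) return("'gamma' must be > 0")
    if (object@tol <= 0 || object@innerTol <= 0)
        return("tolerances must be > 0")
    if (object@maxIter < 1L || object@innerMaxIter < 1L)
        return("iteration limits must be >= 1")
    TRUE
})

#' ADMM iterate state
#'
#' Final iterates and convergence history of the ADMM solver: the primal
#' iterate X (non-negative at every accepted iterate), the auxiliary
#' low-rank iterate Y, the dual multipliers Lambda, and per-iteration
#' traces of the primal residual ||X - Y||_F and of the objective.
#'
#' @slot X,Y,Lambda numeric matrices, cells x genes.
#' @slot k number of ADMM iterations performed.
#' @slot primalResiduals numeric vector of length k.
#' @slot objectiveTrace numeric vector of length k.
#' @slot converged logical, whether the stopping rule was met.
#'
#' @name AdmmState-class
#' @rdname AdmmState-class
#' @exportClass AdmmState
setClass("AdmmState",
    representation(X = "matrix", Y = "matrix", Lambda = "matrix",
                   k = "integer", primalResiduals = "numeric",
                   objectiveTrace = "numeric", converged = "logical"))

setValidity("AdmmState", function(object) {
    if (length(object@primalResiduals) != object@k)
        return("'primalResiduals' must have length k")
    if (any(object@X < 0))
        return("X must be non-negative")
    TRUE
})

#' Precomputed X-update system
#'
#' The linear system behind the ADMM X-subproblem. With a the uniform
#' 1/n averaging row vector, the dense matrix W = beta * a'a + gamma * I
#' equals gamma * I + (beta / n^2) * ones(n, n); only that rank-1-plus-
#' diagonal structure is stored, never the dense matrix. T collects the
#' data-dependent right-hand side beta * a'D + X0.
#'
#' @slot n number of cells.
#' @slot gamma ADMM penalty (diagonal part of W).
#' @slot couplingWeight beta / n^2, the constant off-diagonal entry of W.
#' @slot T numeric matrix beta * a'D + X0.
#' @slot a averaging row vector (each entry 1/n).
#' @slot omegaMask logical matrix of observed (non-zero) entries of X0.
#'
#' @seealso [buildSystem()], [systemW()].
#' @name XUpdateSystem-class
#' @rdname XUpdateSystem-class
#' @exportClass XUpdateSystem
setClass("XUpdateSystem",
    representation(n = "integer", gamma = "numeric",
                   couplingWeight = "numeric", T = "matrix",
                   a = "numeric", omegaMask = "matrix"))

setValidity("XUpdateSystem", function(object) {
    if (abs(sum(object@a) - 1) > 1e-12)
        return("averaging vector 'a' must sum to 1")
    if (!is.logical(object@omegaMask))
        return("'omegaMask' must be logical")
    if (!all(dim(object@omegaMask) == dim(object@T)))
        return("'omegaMask' and 'T' dimensions differ")
    TRUE
})

#' Imputation result
#'
#' The imputed expression matrix together with the solver state and the
#' parameters used.
#'
#' @slot imputed [ScMatrix] of imputed expression values.
#' @slot state [AdmmState] with residual and objective traces.
#' @slot params [ImputeParams] used for the run.
#'
#' @seealso [imputeDropouts()], [imputedMatrix()], [admmState()].
#' @name ImputeResult-class
#' @rdname ImputeResult-class
#' @exportClass ImputeResult
setClass("ImputeResult",
    representation(imputed = "ScMatrix", state = "AdmmState",
                   params = "ImputeParams"))

#' Simulation configuration
#'
#' Parameters of the cluster-structured dropout simulator: the ground
#' truth is built from per-cluster log-normal gene means, perturbed per
#' cell by Gaussian noise with per-gene standard deviation
#' `noiseScale * V_g` (V_g a replicate-level per-gene sd), clamped at 0;
#' dropout zeros are then introduced gene-wise by Bernoulli draws at rate
#' `exp(-lambdaDropout * mean_g^2)`.
#'
#' @slot nCells,nGenes,nClusters positive integers.
#' @slot clusterProps probability vector over clusters, sums to 1.
#' @slot deProb probability a gene is differential between clusters.
#' @slot noiseScale multiplier on the per-gene replicate sd (default 5).
#' @slot lambdaDropout non-negative dropout rate parameter.
#' @slot seed integer random seed.
#'
#' @seealso [simConfig()], [simulateDropoutData()].
#' @name SimConfig-class
#' @rdname SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
    representation(nCells = "integer", nGenes = "integer",
                   nClusters = "integer", clusterProps = "numeric",
                   deProb = "numeric", noiseScale = "numeric",
                   lambdaDropout = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@nCells < 1L || object@nGenes < 1L || object@nClusters < 1L)
        return("dimensions must be positive")
    if (object@nCells < object@nClusters)
        return("need at least one cell per cluster")
    if (length(object@clusterProps) != object@nClusters)
        return("'clusterProps' length must equal 'nClusters'")
    if (any(object@clusterProps <= 0))
        return("'clusterProps' entries must be > 0")
    if (abs(sum(object@clusterProps) - 1) > 1e-12)
        return("'clusterProps' must sum to 1")
    if (object@deProb < 0 || object@deProb > 1)
        return("'deProb' must be in [0, 1]")
    if (object@noiseScale < 0)
        return("'noiseScale' must be >= 0")
    if (object@lambdaDropout < 0)
        return("'lambdaDropout' must be >= 0")
    TRUE
})

#' Simulated ground truth with dropout
#'
#' Output of the simulator: the dropout-free truth matrix, the dropout
#' matrix with introduced zeros, the Bernoulli mask of zeroed entries,
#' per-cell cluster labels, the matched bulk vector (per-gene means of
#' the truth), and the configuration used.
#'
#' @slot truth,dropout numeric matrices, cells x genes.
#' @slot maskDropped logical matrix of entries zeroed by the Bernoulli
#'   dropout process.
#' @slot labels integer cluster label per cell.
#' @slot bulk numeric vector of per-gene means of `truth`.
#' @slot config the [SimConfig] used.
#'
#' @name SimTruth-class
#' @rdname SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth",
    representation(truth = "matrix", dropout = "matrix",
                   maskDropped = "matrix", labels = "integer",
                   bulk = "numeric", config = "SimConfig"))

setValidity("SimTruth", function(object) {
    if (!all(dim(object@truth) == dim(object@dropout)))
        return("'truth' and 'dropout' dimensions differ")
    if (length(object@labels) != nrow(object@truth))
        return("'labels' must have one entry per cell")
    if (length(object@bulk) != ncol(object@truth))
        return("'bulk' must have one entry per gene")
    if (length(object@maskDropped) &&
        !all(dim(object@maskDropped) == dim(object@truth)))
        return("'maskDropped' dimensions differ from 'truth'")
    TRUE
})

#' Pathway gene set
#'
#' A named set of gene identifiers, typically one line of a GMT file,
#' used by the pathway gene correlation score.
#'
#' @slot name pathway name.
#' @slot description free-text description (GMT column 2).
#' @slot genes unique gene identifiers.
#'
#' @seealso [pathwaySet()], [pgcs()], [readPathways()].
#' @name PathwaySet-class
#' @rdname PathwaySet-class
#' @exportClass PathwaySet
setClass("PathwaySet",
    representation(name = "character", description = "character",
                   genes = "character"))

setValidity("PathwaySet", function(object) {
    if (anyDuplicated(object@genes))
        return("pathway genes must be unique")
    if (length(object@genes) < 2L)
        return("a pathway needs at least 2 genes")
    TRUE
})
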