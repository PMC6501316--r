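#' Create imputation parameters
#'
#' The three model weights and the solver controls. The defaults for
#' `alpha`, `beta` and `gamma` are explicit heuristics and should
#' normally be replaced by values tailored to the data scale; see
#' [suggestParams()] for a spectrum-based recommendation. `gamma`
#' affects only the optimisation path, never the optimum of the convex
#' objective.
#'
#' @param alpha nuclear-norm weight (>= 0). Larger values push the
#'   imputed matrix toward fewer effective cell states.
#' @param beta bulk-consistency weight (>= 0) on
#'   `||a X - D||_2^2`, where `a` is the uniform 1/n averaging vector
#'   over cells and `D` the bulk vector.
#' @param gamma positive ADMM penalty.
#' @param maxIter maximum ADMM iterations (default 1000).
#' @param tol relative convergence tolerance: the solver stops when the
#'   primal residual `||X - Y||_F / max(1, ||X0||_F)` and the relative
#'   objective change both fall below `tol` (default 1e-5).
#' @param innerMaxIter maximum Gauss-Seidel sweeps in each X-update
#'   (default 100).
#' @param innerTol relative tolerance of the inner sweeps (default 1e-6).
#'
#' @return An [ImputeParams] object.
#' @examples
#' imputeParams(alpha = 10, beta = 0.5, gamma = 1)
#' @export
imputeParams <- function(alpha = 1, beta = 1e-6, gamma = 1e-4,
                         maxIter = 1000L, tol = 1e-5,
                         innerMaxIter = 100L, innerTol = 1e-6) {
    new("ImputeParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
        gamma = as.numeric(gamma), maxIter = as.integer(maxIter),
        tol = as.numeric(tol), innerMaxIter = as.integer(innerMaxIter),
        innerTol = as.numeric(innerTol))
}

#' @rdname ImputeParams-class
#' @param object an `ImputeParams` object.
#' @export
setMethod("show", "ImputeParams", function(object) {
    cat(sprintf(
        "ImputeParams: alpha=%.4g beta=%.4g gamma=%.4g\n", object@alpha,
        object@beta, object@gamma))
    cat(sprintf("  maxIter=%d tol=%.1e innerMaxIter=%d innerTol=%.1e\n",
                object@maxIter, object@tol, object@innerMaxIter,
                object@innerTol))
})

#' Suggest data-scaled imputation parameters
#'
#' Recommends model weights scaled to the spectrum of the observed
#' matrix, the only guidance the model admits in general: `alpha` is set
#' to a fixed fraction of the top singular value of the raw matrix
#' (so the nuclear-norm pressure is invariant to the expression units),
#' `beta` is proportional to `alpha` and to the matrix size, and
#' `gamma` is chosen so the per-iteration singular-value threshold
#' `alpha / gamma` sits on the scale of the spectrum being retained,
#' which keeps the ADMM iteration count moderate.
#'
#' @param x0 an [ScMatrix] (or numeric matrix, cells x genes).
#' @param alphaFraction fraction of the top singular value used for
#'   `alpha` (default 0.01): small enough that the nuclear norm acts as
#'   a completion tiebreak rather than an aggressive shrinkage of the
#'   observed signal, large enough to keep the ADMM iteration count
#'   moderate.
#' @param betaScale proportionality constant linking `beta` to
#'   `alpha * nCells` (default 0.001). Scaling with the cell count
#'   keeps the per-entry pull of the bulk term, whose gradient carries
#'   a 1/n factor, on a fixed footing relative to the data-fit term.
#' @param ... further arguments passed to [imputeParams()].
#'
#' @return An [ImputeParams] object.
#' @examples
#' set.seed(1)
#' x <- ScMatrix(matrix(rexp(60), 6, 10))
#' suggestParams(x)
#' @export
suggestParams <- function(x0, alphaFraction = 0.01, betaScale = 0.001, ...) {
    v <- if (is(x0, "ScMatrix")) exprValues(x0) else as.matrix(x0)
    sigma1 <- svd(v, nu = 0L, nv = 0L)$d[1L]
    if (!is.finite(sigma1) || sigma1 <= 0)
        .sbiStop("sbiDegenerateInputError",
                 "cannot suggest parameters for an all-zero matrix")
    alpha <- alphaFraction * sigma1
    beta <- betaScale * alpha * nrow(v)
    gamma <- alpha / (0.25 * sigma1)
    imputeParams(alpha = alpha, beta = beta, gamma = gamma, ...)
}
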