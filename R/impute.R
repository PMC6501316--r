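#' Impute dropout zeros by bulk-constrained low-rank matrix completion
#'
#' Recovers a non-negative expression matrix `X` from a raw single-cell
#' matrix `x0` with dropout zeros and a matched bulk vector `d` by
#' minimising the convex objective
#'
#' `0.5 * ||P_Omega(X) - X0||_F^2 + alpha * ||X||_* + beta * ||aX - D||_2^2`
#' subject to `X >= 0`,
#'
#' where the observed set Omega is the non-zero pattern of `x0`, the
#' nuclear norm encourages few effective cell states, and the last term
#' ties the per-gene cell averages to the bulk profile. The problem is
#' solved by ADMM: an exact projected Gauss-Seidel X-update
#' ([xUpdate()]), a singular value thresholding Y-update ([yUpdate()]),
#' and the dual step ([lambdaUpdate()]). Iterates start at
#' `X = Y = x0`, `Lambda = 0`, and the loop stops when both the relative
#' primal residual `||X - Y||_F / max(1, ||X0||_F)` and the relative
#' objective change fall below `tol`, or at `maxIter`. The optimiser is
#' fully deterministic.
#'
#' The solver operates on the matrix as given; library-size
#' normalisation and a log1p transform upstream are recommended for
#' count-like data, with the bulk vector on the same transform. No
#' transform is applied silently.
#'
#' @param x0 an [ScMatrix] (cells x genes) or a plain non-negative
#'   matrix.
#' @param d a [BulkVector] aligned to the genes of `x0`, or a numeric
#'   vector of per-gene bulk averages in the same order.
#' @param params an [ImputeParams]; see [suggestParams()] for
#'   data-scaled values.
#' @param divergeAfter declare divergence (and raise a
#'   `sbiConvergenceError` carrying the residual trace) if the primal
#'   residual increases this many consecutive iterations while above its
#'   starting value.
#'
#' @return An [ImputeResult]: the imputed [ScMatrix] (non-negative,
#'   names preserved) and the [AdmmState] with residual and objective
#'   traces.
#' @examples
#' set.seed(7)
#' truth <- outer(rexp(8, 1 / 4), rexp(12, 1 / 3))
#' drop <- truth * (matrix(runif(96), 8) > 0.4)
#' res <- imputeDropouts(ScMatrix(drop), colMeans(truth),
#'                       imputeParams(alpha = 2, beta = 1, gamma = 1))
#' res
#' @export
imputeDropouts <- function(x0, d, params = imputeParams(),
                           divergeAfter = 50L) {
    if (!is(x0, "ScMatrix")) x0 <- ScMatrix(x0)
    x0v <- exprValues(x0)
    if (all(x0v == 0))
        .sbiStop("sbiDegenerateInputError",
                 "input matrix is all zero: nothing is observed")
    # Stationarity of the X-subproblem differentiates beta*||aX - D||^2,
    # which carries a factor 2; the linear system is therefore assembled
    # with weight 2*beta so the loop minimises the stated objective.
    sysParams <- params
    sysParams@beta <- 2 * params@beta
    system <- buildSystem(x0, d, sysParams)
    gamma <- params@gamma
    X <- x0v
    Y <- x0v
    Lambda <- array(0, dim(x0v))
    scale0 <- max(1, sqrt(sum(x0v^2)))
    primal <- numeric(0)
    objs <- numeric(0)
    converged <- FALSE
    nIncrease <- 0L
    dv <- if (is(d, "BulkVector")) d@values else as.numeric(d)
    for (k in seq_len(params@maxIter)) {
        X <- xUpdate(system, Y, Lambda, params, Xinit = X)
        Y <- yUpdate(X, Lambda, params)
        Lambda <- lambdaUpdate(Lambda, X, Y, gamma)
        r <- sqrt(sum((X - Y)^2)) / scale0
        primal <- c(primal, r)
        objs <- c(objs, objectiveValue(X, x0v, dv, params))
        if (k >= 2L) {
            relObj <- abs(objs[k] - objs[k - 1L]) / max(1, abs(objs[k - 1L]))
            if (r < params@tol && relObj < params@tol) {
                converged <- TRUE
                break
            }
            nIncrease <- if (r > primal[k - 1L] && r > primal[1L])
                nIncrease + 1L else 0L
            if (nIncrease >= divergeAfter) {
                cond <- structure(
                    class = c("sbiConvergenceError", "sbiError", "error",
                              "condition"),
                    list(message = sprintf(
                             "primal residual increased for %d consecutive iterations (last %.3g)",
                             nIncrease, r),
                         call = sys.call(-1),
                         primalResiduals = primal, objectiveTrace = objs))
                stop(cond)
            }
        }
    }
    state <- new("AdmmState", X = X, Y = Y, Lambda = Lambda,
                 k = length(primal), primalResiduals = primal,
                 objectiveTrace = objs, converged = converged)
    imputed <- ScMatrix(X, geneNames = geneNames(x0),
                        cellNames = cellNames(x0))
    new("ImputeResult", imputed = imputed, state = state, params = params)
}
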