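.checkSameDim <- function(A, B, what = "matrices") {
    if (!all(dim(A) == dim(B)))
        .sbiStop("sbiDimensionError",
                 sprintf("%s have incompatible dimensions (%s vs %s)", what,
                         paste(dim(A), collapse = "x"),
                         paste(dim(B), collapse = "x")))
}

.checkFinite <- function(A, what = "matrix") {
    if (any(!is.finite(A)))
        .sbiStop("sbiNumericError",
                 sprintf("%s contains non-finite values", what))
}

#' Project a matrix onto the observed-entry set
#'
#' Keeps entries where `omegaMask` is `TRUE` and zeroes all others. The
#' observed set of an expression matrix is the set of its non-zero
#' entries, so this is the operator that restricts a candidate imputed
#' matrix to the entries actually measured.
#'
#' @param X numeric matrix.
#' @param omegaMask logical matrix of the same shape.
#'
#' @return A matrix of the same shape, zero outside the mask.
#' @examples
#' projectOmega(matrix(1:4, 2), matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
#' @export
projectOmega <- function(X, omegaMask) {
    .checkSameDim(X, omegaMask, "'X' and 'omegaMask'")
    X * (omegaMask != 0)
}

#' Value of the imputation objective
#'
#' Evaluates the convex objective
#' `0.5 * ||P_Omega(X) - X0||_F^2 + alpha * ||X||_* + beta * ||a X - D||_2^2`
#' at a candidate matrix `X`, where `P_Omega` keeps the entries observed
#' (non-zero) in `x0`, `||.||_*` is the nuclear norm (sum of singular
#' values), and `a` is the uniform averaging vector over cells so that
#' `a X` is the vector of per-gene means. Negative entries in `X` are
#' permitted here: the function evaluates, it does not constrain.
#'
#' @param X numeric matrix (cells x genes).
#' @param x0 an [ScMatrix] or numeric matrix of raw observed expression.
#' @param d a [BulkVector] or numeric vector of per-gene bulk averages.
#' @param params an [ImputeParams].
#'
#' @return A single non-negative number.
#' @examples
#' x0 <- matrix(c(1, 2, 3, 4), 2)
#' objectiveValue(x0, x0, colMeans(x0), imputeParams(alpha = 0))
#' @export
objectiveValue <- function(X, x0, d, params) {
    x0v <- if (is(x0, "ScMatrix")) exprValues(x0) else as.matrix(x0)
    dv <- if (is(d, "BulkVector")) d@values else as.numeric(d)
    .checkSameDim(X, x0v, "'X' and 'x0'")
    if (length(dv) != ncol(x0v))
        .sbiStop("sbiDimensionError", "bulk vector length must equal gene count")
    .checkFinite(X, "'X'")
    omega <- x0v != 0
    fit <- 0.5 * sum((X[omega] - x0v[omega])^2)
    nuc <- if (params@alpha > 0) params@alpha * sum(svd(X, nu = 0, nv = 0)$d)
           else 0
    bulkResid <- colMeans(X) - dv
    fit + nuc + params@beta * sum(bulkResid^2)
}

#' Build the X-update linear system
#'
#' Precomputes the quantities of the ADMM X-subproblem: with `a` the
#' uniform 1/n averaging row vector, `W = beta * a'a + gamma * I` and
#' `T = beta * a'D + X0`. `W` equals
#' `gamma * I + (beta / n^2) * ones(n, n)`; only this rank-1-plus-
#' diagonal structure is stored ([systemW()] materialises the dense
#' matrix for inspection).
#'
#' @param x0 an [ScMatrix].
#' @param d a [BulkVector] aligned to the genes of `x0`, or a plain
#'   numeric vector in the same gene order.
#' @param params an [ImputeParams].
#'
#' @return An [XUpdateSystem].
#' @examples
#' x0 <- ScMatrix(matrix(c(1, 0, 2, 3), 2))
#' buildSystem(x0, colMeans(exprValues(x0)), imputeParams())
#' @export
buildSystem <- function(x0, d, params) {
    x0v <- exprValues(x0)
    n <- nrow(x0v)
    if (is(d, "BulkVector")) {
        if (!identical(d@geneNames, geneNames(x0))) {
            bad <- union(setdiff(d@geneNames, geneNames(x0)),
                         setdiff(geneNames(x0), d@geneNames))
            if (length(bad) == 0L) bad <- "(same set, different order)"
            .sbiStop("sbiAlignmentError",
                     paste0("bulk genes are not aligned to the matrix: ",
                            paste(head(bad, 10L), collapse = ", ")))
        }
        dv <- d@values
    } else dv <- as.numeric(d)
    if (length(dv) != ncol(x0v))
        .sbiStop("sbiDimensionError", "bulk vector length must equal gene count")
    a <- rep(1 / n, n)
    # T = beta * a'D + X0: beta * a'D has every row equal to (beta/n) * D
    Tm <- x0v + matrix(params@beta / n * dv, n, length(dv), byrow = TRUE)
    new("XUpdateSystem", n = as.integer(n), gamma = params@gamma,
        couplingWeight = params@beta / n^2, T = Tm, a = a,
        omegaMask = x0v != 0)
}

#' @rdname XUpdateSystem-class
#' @param system an [XUpdateSystem].
#' @return `systemW()` returns the dense n x n matrix
#'   `gamma * I + (beta/n^2) * ones`.
#' @export
systemW <- function(system) {
    n <- system@n
    diag(system@gamma, n) + matrix(system@couplingWeight, n, n)
}

#' @rdname XUpdateSystem-class
#' @param object an `XUpdateSystem` object.
#' @export
setMethod("show", "XUpdateSystem", function(object) {
    cat(sprintf(
        "XUpdateSystem: %d cells x %d genes, gamma=%.4g, coupling=%.4g\n",
        object@n, ncol(object@T), object@gamma, object@couplingWeight))
})

#' ADMM X-update (projected Gauss-Seidel)
#'
#' Solves the bound-constrained X-subproblem
#' `P_Omega(X) + W X = gamma * Y + T - Lambda`, subject to `X >= 0`,
#' by coordinate-wise Gauss-Seidel sweeps with a non-negative clamp.
#' Because the subproblem is a strictly convex quadratic over the
#' non-negative orthant and each coordinate update is an exact
#' one-dimensional minimisation, the sweeps converge to the unique
#' subproblem optimum; at entries where the clamp is inactive the linear
#' system holds exactly. The rank-1-plus-diagonal structure of `W` is
#' exploited through running column sums, so a full sweep costs O(nm).
#'
#' @param system an [XUpdateSystem] from [buildSystem()].
#' @param Y,Lambda current auxiliary and dual iterates (cells x genes).
#' @param params an [ImputeParams] (supplies the sweep controls).
#' @param Xinit optional warm start (defaults to `Y` clamped at 0).
#'
#' @return The updated non-negative matrix X.
#' @export
xUpdate <- function(system, Y, Lambda, params, Xinit = NULL) {
    .checkSameDim(Y, system@T, "'Y' and the system")
    .checkSameDim(Lambda, system@T, "'Lambda' and the system")
    .checkFinite(Y, "'Y'")
    .checkFinite(Lambda, "'Lambda'")
    rhs <- system@gamma * Y + system@T - Lambda
    if (is.null(Xinit)) Xinit <- pmax(Y, 0)
    storage.mode(Xinit) <- "double"
    omega <- matrix(as.integer(system@omegaMask), system@n)
    x_update_sweeps(rhs, omega, system@gamma, system@couplingWeight,
                    Xinit, params@innerMaxIter, params@innerTol)
}

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: given the singular value
#' decomposition `Z = U diag(sigma) V'`, returns
#' `U diag(max(sigma - tau, 0)) V'`. Singular values at or below `tau`
#' are annihilated.
#'
#' @param Z numeric matrix.
#' @param tau positive threshold.
#'
#' @return A matrix of the same shape with a soft-thresholded spectrum.
#' @examples
#' svt(diag(c(3, 1)), 1)
#' @export
svt <- function(Z, tau) {
    if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
        .sbiStop("sbiParameterError", "'tau' must be a single positive number")
    .checkFinite(Z, "'Z'")
    s <- svd(Z)
    keep <- pmax(s$d - tau, 0)
    r <- sum(keep > 0)
    if (r == 0L) return(array(0, dim(Z)))
    s$u[, seq_len(r), drop = FALSE] %*%
        (keep[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
}

#' ADMM Y-update (nuclear-norm proximal step)
#'
#' Minimises
#' `(alpha/gamma) * ||Y||_* + 0.5 * ||Lambda/gamma + X - Y||_F^2`,
#' whose solution is `svt(X + Lambda/gamma, alpha/gamma)`. With
#' `alpha = 0` the threshold vanishes and `Y = X + Lambda/gamma`.
#'
#' @param X current primal iterate.
#' @param Lambda current dual iterate.
#' @param params an [ImputeParams] (uses `alpha` and `gamma`).
#'
#' @return The updated matrix Y.
#' @export
yUpdate <- function(X, Lambda, params) {
    .checkSameDim(X, Lambda, "'X' and 'Lambda'")
    if (params@gamma <= 0)
        .sbiStop("sbiParameterError", "'gamma' must be > 0")
    Z <- X + Lambda / params@gamma
    if (params@alpha == 0) return(Z)
    svt(Z, params@alpha / params@gamma)
}

#' ADMM dual update
#'
#' The multiplier step `Lambda + gamma * (X - Y)`.
#'
#' @param Lambda,X,Y conforming numeric matrices.
#' @param gamma positive ADMM penalty.
#'
#' @return The updated multiplier matrix.
#' @examples
#' lambdaUpdate(matrix(0, 2, 2), diag(2), matrix(0, 2, 2), gamma = 2)
#' @export
lambdaUpdate <- function(Lambda, X, Y, gamma) {
    .checkSameDim(Lambda, X, "'Lambda' and 'X'")
    .checkSameDim(X, Y, "'X' and 'Y'")
    if (gamma <= 0)
        .sbiStop("sbiParameterError", "'gamma' must be > 0")
    Lambda + gamma * (X - Y)
}
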