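# Independent oracles. Deliberately use no package internals beyond the
# exported evaluation surface: singular values come from eigen() on the
# Gram matrix, proximal steps are written inline.

# nuclear norm from eigen(A'A) -- independent of svd()-based code paths
oracleNuclearNorm <- function(A) {
    ev <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
    sum(sqrt(pmax(ev, 0)))
}

# full objective recomputed term by term, by direct summation
oracleObjective <- function(X, x0, d, alpha, beta) {
    omega <- x0 != 0
    fit <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X)))
        if (omega[i, j]) fit <- fit + (X[i, j] - x0[i, j])^2
    bulk <- 0
    for (j in seq_len(ncol(X)))
        bulk <- bulk + (mean(X[, j]) - d[j])^2
    0.5 * fit + alpha * oracleNuclearNorm(X) + beta * bulk
}

# inline SVT via eigen decompositions (not the package's svt())
oracleSvt <- function(Z, tau) {
    s <- La.svd(Z)
    keep <- pmax(s$d - tau, 0)
    s$u %*% (keep * s$vt)
}

# Davis-Yin three-operator splitting for
#   min 0.5||P_Omega(X)-X0||_F^2 + beta||aX-D||_2^2  (smooth, f)
#     + alpha||X||_*  (g2)  + indicator(X>=0)  (g1)
# Converges to the exact optimum of the convex problem; algorithmically
# unrelated to the package's ADMM path.
oracleSolve <- function(x0, d, alpha, beta, maxIter = 50000, tol = 1e-12) {
    n <- nrow(x0)
    omega <- x0 != 0
    L <- 1 + 2 * beta / n
    eta <- 1 / L
    gradf <- function(X) {
        (X - x0) * omega +
            matrix(2 * beta / n * (colMeans(X) - d), n, ncol(x0),
                   byrow = TRUE)
    }
    Z <- x0
    xB <- x0
    for (k in seq_len(maxIter)) {
        xB_new <- pmax(Z, 0)
        xA <- oracleSvt(2 * xB_new - Z - eta * gradf(xB_new), eta * alpha)
        Z <- Z + xA - xB_new
        if (max(abs(xB_new - xB)) < tol && k > 10) {
            xB <- xB_new
            break
        }
        xB <- xB_new
    }
    pmax(xB, 0)
}

# dense per-column solve of the X-subproblem when the clamp is inactive:
# (W + diag(omega_col)) x_col = rhs_col
oracleXUpdateDense <- function(x0, d, alpha, beta, gamma, Y, Lambda) {
    n <- nrow(x0)
    W <- diag(gamma, n) + matrix(beta / n^2, n, n)
    Tm <- x0 + matrix(beta / n * d, n, ncol(x0), byrow = TRUE)
    rhs <- gamma * Y + Tm - Lambda
    omega <- x0 != 0
    X <- matrix(0, n, ncol(x0))
    for (j in seq_len(ncol(x0)))
        X[, j] <- solve(W + diag(as.numeric(omega[, j])), rhs[, j])
    X
}

# brute-force two-sample KS: sup over all pooled jump points
oracleKs <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(vapply(pts, function(t)
        abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# O(p^2) pairwise-Pearson comparison of correlation structures
oracleCorrelationPreservation <- function(truth, other, axis) {
    if (axis == "cells") { truth <- t(truth); other <- t(other) }
    p <- ncol(truth)
    ut <- c(); uo <- c()
    for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
        ut <- c(ut, cor(truth[, i], truth[, j]))
        uo <- c(uo, cor(other[, i], other[, j]))
    }
    ok <- is.finite(ut) & is.finite(uo)
    cor(ut[ok], uo[ok])
}
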