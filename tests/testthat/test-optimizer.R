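test_that("projectOmega applies the mask and is an idempotent contraction", {
    X <- matrix(c(1, 3, 2, 4), 2)
    expect_equal(projectOmega(X, matrix(TRUE, 2, 2)), X)
    expect_equal(projectOmega(X, matrix(FALSE, 2, 2)), matrix(0, 2, 2))
    mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
    expect_equal(projectOmega(X, mask), matrix(c(1, 0, 0, 4), 2))
    expect_error(projectOmega(X, matrix(TRUE, 3, 2)), "dimensions")
    for (s in 1:5) {
        set.seed(s)
        Z <- matrix(rnorm(20), 4)
        m <- matrix(runif(20) > 0.5, 4)
        p1 <- projectOmega(Z, m)
        expect_equal(projectOmega(p1, m), p1)          # idempotent
        expect_lte(frob(p1), frob(Z))                  # contraction
    }
})

test_that("objectiveValue matches a term-by-term brute-force oracle", {
    # all penalties vanish at the data when nothing is missing
    x0 <- matrix(c(1, 2, 3, 4), 2)
    expect_equal(objectiveValue(x0, x0, colMeans(x0),
                                imputeParams(alpha = 0, beta = 2)), 0)
    z <- matrix(0, 2, 2)
    expect_equal(objectiveValue(z, z, c(0, 0), imputeParams(alpha = 5)), 0)
    set.seed(11)
    X <- matrix(rnorm(12), 4)
    x0 <- matrix(rexp(12), 4)
    x0[sample(12, 4)] <- 0
    d <- rexp(3)
    got <- objectiveValue(X, x0, d, imputeParams(alpha = 1, beta = 2))
    expect_equal(got, oracleObjective(X, x0, d, alpha = 1, beta = 2),
                 tolerance = 1e-12)
    expect_error(objectiveValue(matrix(NaN, 4, 3), x0, d, imputeParams()),
                 "non-finite")
})

test_that("buildSystem forms W and T as defined", {
    x0 <- randomScMatrix(2, 3, seed = 2)
    sys0 <- buildSystem(x0, colMeans(exprValues(x0)),
                        imputeParams(beta = 0, gamma = 1))
    expect_equal(systemW(sys0), diag(2))
    expect_equal(sys0@T, exprValues(x0))

    x4 <- randomScMatrix(4, 3, seed = 3)
    sys4 <- buildSystem(x4, colMeans(exprValues(x4)),
                        imputeParams(beta = 1, gamma = 2))
    expect_equal(systemW(sys4), diag(2, 4) + matrix(1 / 16, 4, 4))
    expect_equal(sum(sys4@a), 1)

    # T = beta * a'(a X0) + X0 when the bulk is the cell average
    a <- matrix(rep(1 / 4, 4), 1)
    v <- exprValues(x4)
    expect_equal(sys4@T, v + 1 * t(a) %*% (a %*% v))

    bulkShuffled <- BulkVector(colMeans(v), rev(geneNames(x4)))
    expect_error(buildSystem(x4, bulkShuffled, imputeParams()),
                 "not aligned")
})

test_that("xUpdate solves the clamped per-column linear system", {
    # empty Omega with beta = 0 reduces to gamma X = gamma Y
    n <- 4; m <- 3
    zeros <- ScMatrix(matrix(0, n, m))
    p <- imputeParams(beta = 0, gamma = 1.7)
    sys <- buildSystem(zeros, rep(0, m), p)
    set.seed(4)
    Y <- matrix(rexp(n * m), n)
    expect_equal(xUpdate(sys, Y, matrix(0, n, m), p), Y)

    # full Omega with beta = 0: closed form (gamma Y + X0) / (1 + gamma)
    x0 <- randomScMatrix(n, m, seed = 5)
    sys2 <- buildSystem(x0, colMeans(exprValues(x0)), p)
    X <- xUpdate(sys2, Y, matrix(0, n, m), p)
    expect_equal(X, unname(pmax((1.7 * Y + exprValues(x0)) / 2.7, 0)),
                 tolerance = 1e-9)

    # strictly positive solution matches a dense per-column solve and
    # satisfies the linear system to high accuracy
    set.seed(6)
    x05 <- randomScMatrix(5, 3, zeroFrac = 0.3, seed = 6)
    v <- exprValues(x05)
    d <- colMeans(v)
    p2 <- imputeParams(alpha = 1, beta = 0.5, gamma = 1,
                       innerMaxIter = 500, innerTol = 1e-13)
    sys3 <- buildSystem(x05, d, p2)
    Y2 <- matrix(rexp(15, 1 / 4), 5) + 1
    L2 <- matrix(rnorm(15, sd = 0.01), 5)
    X2 <- xUpdate(sys3, Y2, L2, p2)
    dense <- oracleXUpdateDense(v, d, 1, 0.5, 1, Y2, L2)
    expect_true(all(dense > 0))  # fixture keeps the clamp inactive
    expect_equal(X2, dense, tolerance = 1e-8)
    rhs <- 1 * Y2 + sys3@T - L2
    resid <- projectOmega(X2, sys3@omegaMask) + systemW(sys3) %*% X2 - rhs
    expect_lt(frob(resid), 1e-8)
    expect_error(xUpdate(sys3, Y2 * NA, L2, p2), "non-finite")
})

test_that("svt soft-thresholds the singular spectrum", {
    expect_equal(svt(diag(c(3, 1)), 1), diag(c(2, 0)))
    expect_equal(svt(matrix(0, 3, 2), 5), matrix(0, 3, 2))
    set.seed(7)
    Z <- matrix(rnorm(24), 6)
    got <- svt(Z, 0.7)
    expect_equal(got, oracleSvt(Z, 0.7), tolerance = 1e-10)
    sv <- svd(Z, nu = 0, nv = 0)$d
    expect_equal(oracleNuclearNorm(got), sum(pmax(sv - 0.7, 0)),
                 tolerance = 1e-8)
    # no singular value ever grows
    expect_true(all(svd(got, nu = 0, nv = 0)$d <= sv + 1e-10))
    expect_error(svt(Z, 0), "tau")
})

test_that("svt is 1-Lipschitz in Frobenius norm", {
    for (s in 1:8) {
        set.seed(s)
        A <- matrix(rnorm(20), 5)
        B <- matrix(rnorm(20), 5)
        expect_lte(frob(svt(A, 0.5) - svt(B, 0.5)), frob(A - B) + 1e-12)
    }
})

test_that("yUpdate is the nuclear-norm proximal map", {
    X <- matrix(c(1, 2, 3, 4), 2)
    L <- matrix(c(0.5, 0, 0, 0.5), 2)
    expect_equal(yUpdate(X, L, imputeParams(alpha = 0, gamma = 2)),
                 X + L / 2)
    expect_equal(yUpdate(diag(c(5, 1)), matrix(0, 2, 2),
                         imputeParams(alpha = 2, gamma = 1)),
                 diag(c(3, 0)))
    # optimality of the prox objective against random perturbations
    set.seed(8)
    X <- matrix(rnorm(4), 2)
    L <- matrix(rnorm(4), 2)
    p <- imputeParams(alpha = 0.8, gamma = 1.3)
    Ystar <- yUpdate(X, L, p)
    h <- function(Y) (p@alpha / p@gamma) * oracleNuclearNorm(Y) +
        0.5 * frob(L / p@gamma + X - Y)^2
    for (i in 1:200) {
        delta <- matrix(rnorm(4, sd = sample(c(1e-3, 0.1, 1), 1)), 2)
        expect_gte(h(Ystar + delta), h(Ystar) - 1e-10)
    }
})

test_that("lambdaUpdate is exact affine algebra", {
    L <- matrix(c(1, 2, 3, 4), 2)
    X <- matrix(c(1, 0, 0, 1), 2)
    expect_equal(lambdaUpdate(L, X, X, 3), L)
    D <- matrix(c(1, 0, 0, -1), 2)
    expect_equal(lambdaUpdate(matrix(0, 2, 2), D, matrix(0, 2, 2), 2),
                 2 * D)
    once <- lambdaUpdate(L, X + D, X, 1.5)
    twice <- lambdaUpdate(once, X + D, X, 1.5)
    expect_equal(twice, L + 2 * 1.5 * D)
    expect_error(lambdaUpdate(L, X, X, -1), "gamma")
})
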