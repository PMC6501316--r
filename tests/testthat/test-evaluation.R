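test_that("imputationError is the Frobenius norm of the difference", {
    A <- matrix(c(1, 2, 3, 4), 2)
    expect_equal(imputationError(A, A), 0)
    expect_equal(imputationError(A + matrix(c(3, 0, 0, 4), 2), A), 5)
    set.seed(1)
    X <- matrix(rexp(35), 5); Y <- matrix(rexp(35), 5)
    expect_equal(imputationError(X, Y), sqrt(sum((X - Y)^2)))
    # spectral option is the largest singular value of the difference
    expect_equal(imputationError(X, Y, norm = "spectral"),
                 max(svd(X - Y)$d))
    expect_error(imputationError(X, matrix(0, 2, 2)), "dimensions")
})

test_that("imputationError satisfies the triangle inequality", {
    for (s in 1:5) {
        set.seed(s)
        A <- matrix(rnorm(24), 4); B <- matrix(rnorm(24), 4)
        C <- matrix(rnorm(24), 4)
        expect_lte(imputationError(A, C),
                   imputationError(A, B) + imputationError(B, C) + 1e-12)
    }
})

test_that("ksStatistic matches the brute-force ECDF supremum", {
    expect_equal(ksStatistic(c(1, 5, 9), c(1, 5, 9)), 0)
    expect_equal(ksStatistic(c(0, 0, 0), c(1, 1, 1)), 1)
    expect_equal(ksStatistic(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
    for (s in 1:6) {
        set.seed(s)
        a <- round(rexp(40), 1)  # rounding forces ties
        b <- round(rexp(25, 0.8), 1)
        d <- ksStatistic(a, b)
        expect_equal(d, oracleKs(a, b))
        expect_equal(d, ksStatistic(b, a))  # symmetric
        expect_gte(d, 0); expect_lte(d, 1)
    }
    expect_equal(ksStatistic(c(0, 1), c(0, 1), log1pTransform = TRUE), 0)
    expect_error(ksStatistic(numeric(0), 1), class = "sbiDomainError")
})

test_that("correlationPreservation compares correlation structures", {
    set.seed(2)
    truth <- matrix(rexp(20 * 30), 20)
    expect_equal(correlationPreservation(truth, truth, "cells"), 1)
    # simultaneous relabeling leaves the comparison invariant
    perm <- sample(20)
    expect_equal(correlationPreservation(truth[perm, ], truth[perm, ],
                                         "cells"), 1)
    other <- truth + matrix(rnorm(600, sd = 0.5), 20)
    got <- correlationPreservation(truth, other, "cells")
    expect_equal(got, oracleCorrelationPreservation(truth, other, "cells"),
                 tolerance = 1e-12)
    gotG <- correlationPreservation(truth, other, "genes")
    expect_equal(gotG, oracleCorrelationPreservation(truth, other, "genes"),
                 tolerance = 1e-12)
    expect_error(correlationPreservation(truth[1:2, ], other[1:2, ], "cells"),
                 class = "sbiDomainError")
    # zero-variance items are dropped pairwise, with a message
    t2 <- truth; t2[, 1] <- 3
    expect_message(correlationPreservation(t2, other, "genes"), "dropped")
})

test_that("clusterDistortion is zero when structure is preserved", {
    set.seed(3)
    truth <- matrix(rexp(12 * 20), 12)
    labels <- rep(1:2, each = 6)
    expect_equal(clusterDistortion(truth, truth, labels), 0)

    # block construction: within-correlation 1, between-correlation -1
    v <- rexp(20) + 1
    block <- rbind(matrix(rep(v, 6), 6, byrow = TRUE),
                   matrix(rep(max(v) + 1 - v, 6), 6, byrow = TRUE))
    noise <- matrix(rnorm(240, sd = 1e-9), 12)  # break exact constancy
    bm <- block + noise
    pc <- suppressWarnings(cor(t(bm)))
    expect_equal(clusterDistortion(bm, 2 * bm, labels), 0, tolerance = 1e-12)
    # and its truth-side KS is exactly 1 (disjoint distributions)
    within <- pc[1:6, 1:6][upper.tri(pc[1:6, 1:6])]
    between <- as.numeric(pc[1:6, 7:12])
    expect_equal(ksStatistic(within, between), 1)

    expect_error(clusterDistortion(truth, truth, rep(1, 12)),
                 class = "sbiDomainError")
})

test_that("gene_marker distortion mode stratifies marker pairs", {
    sim <- simulateDropoutData(simConfig(nCells = 60, nGenes = 100,
                                         deProb = 0.3, seed = 31), 0.5)
    truth <- truthMatrix(sim)
    suppressMessages({
        d0 <- clusterDistortion(truth, truth, clusterLabels(sim),
                                mode = "gene_marker", nMarkers = 20)
        d1 <- clusterDistortion(truth, dropoutMatrix(sim), clusterLabels(sim),
                                mode = "gene_marker", nMarkers = 20)
    })
    expect_equal(d0, 0)
    expect_gte(d1, 0); expect_lte(d1, 1)
})

test_that("pgcs detects coherent pathway co-expression", {
    set.seed(4)
    n <- 50; m <- 60
    mat <- matrix(rexp(n * m), n)
    colnames(mat) <- paste0("g", seq_len(m))
    signal <- rexp(n)
    # pathway columns share one signal, background is independent noise
    for (j in 1:5) mat[, j] <- signal + rnorm(n, sd = 0.05)
    pw <- pathwaySet("coexpressed", paste0("g", 1:5))
    score <- pgcs(mat, pw, nRandom = 50, seed = 7)
    expect_gt(score, 0.5)
    # reproducible bit-for-bit with the same seed
    expect_identical(score, pgcs(mat, pw, nRandom = 50, seed = 7))
    # a random pathway is exchangeable with its background: mean near 0
    nulls <- vapply(1:30, function(i) {
        set.seed(100 + i)
        pgcs(mat[, 6:60], sample(paste0("g", 6:60), 5), nRandom = 40,
             seed = i)
    }, numeric(1))
    expect_lt(abs(mean(nulls)), 0.05)
    expect_warning(p <- pgcs(mat, pathwaySet("unmapped", c("zz1", "zz2"))),
                   "fewer than 2")
    expect_true(is.na(p))
})

test_that("pgcs Monte-Carlo noise shrinks with more background draws", {
    set.seed(5)
    mat <- matrix(rexp(40 * 80), 40)
    colnames(mat) <- paste0("g", 1:80)
    pw <- paste0("g", 1:6)
    est <- function(nr) vapply(1:25, function(i) pgcs(mat, pw, nRandom = nr,
                                                      seed = 1000 + i),
                               numeric(1))
    expect_gt(var(est(1)) / var(est(25)), 5)
})

test_that("deltaPgcs is an antisymmetric paired difference", {
    set.seed(6)
    raw <- matrix(rexp(30 * 40), 30)
    colnames(raw) <- paste0("g", 1:40)
    pw <- paste0("g", 1:5)
    expect_equal(deltaPgcs(raw, raw, pw, nRandom = 20, seed = 3), 0)
    imp <- raw
    common <- rexp(30)
    for (j in 1:5) imp[, j] <- common + rnorm(30, sd = 0.1)
    d <- deltaPgcs(imp, raw, pw, nRandom = 20, seed = 3)
    expect_gt(d, 0)
    expect_equal(deltaPgcs(raw, imp, pw, nRandom = 20, seed = 3), -d)
})

test_that("dunnIndex implements the classic ratio", {
    pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
    got <- dunnIndex(pts, c(1, 1, 2, 2))
    expect_equal(got, sqrt(181))  # nearest inter pair (0,1)-(10,10), diam 1
    # positive scaling and isometry leave the index unchanged
    expect_equal(dunnIndex(pts * 3.7, c(1, 1, 2, 2)), got)
    rot <- matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2)
    expect_equal(dunnIndex(pts %*% rot + 5, c(1, 1, 2, 2)), got)
    # overlapping clusters score poorly
    set.seed(7)
    cloud <- matrix(rnorm(60), 30)
    expect_lt(dunnIndex(cloud, rep(1:2, 15)), 1)
    # all-duplicate clusters have zero diameter
    dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
    expect_identical(dunnIndex(dup, c(1, 1, 2, 2)), Inf)
    expect_error(dunnIndex(pts, rep(1, 4)), class = "sbiDomainError")
})

test_that("evaluateImputation assembles a finite report", {
    sim <- simulateDropoutData(simConfig(nCells = 40, nGenes = 60, seed = 32),
                               0.5)
    x0 <- ScMatrix(dropoutMatrix(sim))
    res <- imputeDropouts(x0, bulkVector(sim), suggestParams(x0))
    pw <- pathwaySet("p1", paste0("gene", 1:6))
    rep <- suppressMessages(evaluateImputation(
        truthMatrix(sim), imputedMatrix(res), dropout = dropoutMatrix(sim),
        labels = clusterLabels(sim), pathways = pw, nRandom = 10))
    expect_true(all(c("imputationError", "ksStatistic",
                      "cellCorrelationPreservation", "dropoutError",
                      "clusterDistortion", "dunnIndexImputed") %in%
                    names(rep)))
    scalars <- unlist(rep[setdiff(names(rep), "pathways")])
    expect_true(all(is.finite(scalars)))
})
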