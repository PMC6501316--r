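#' Create a simulation configuration
#'
#' Defaults mirror common strategy choices for cluster-structured
#' dropout benchmarks: three clusters of proportions 0.2/0.35/0.45, a
#' differential-expression probability of 0.045, and Gaussian cell-level
#' noise with standard deviation 5 times the per-gene replicate-level
#' standard deviation.
#'
#' @param nCells,nGenes,nClusters dimensions of the simulation.
#' @param clusterProps cluster proportions (positive, sum to 1).
#' @param deProb probability a gene is differential between clusters.
#' @param noiseScale multiplier on the per-gene replicate sd (default 5).
#' @param lambdaDropout dropout rate parameter of
#'   `exp(-lambda * mean^2)`; use [calibrateLambda()] to target a zero
#'   fraction instead.
#' @param seed integer random seed.
#'
#' @return A [SimConfig].
#' @examples
#' simConfig(nCells = 100, nGenes = 200, seed = 1)
#' @export
simConfig <- function(nCells = 800L, nGenes = 5000L, nClusters = 3L,
                      clusterProps = c(0.2, 0.35, 0.45), deProb = 0.045,
                      noiseScale = 5, lambdaDropout = 0.01, seed = 1L) {
    new("SimConfig", nCells = as.integer(nCells), nGenes = as.integer(nGenes),
        nClusters = as.integer(nClusters),
        clusterProps = as.numeric(clusterProps), deProb = as.numeric(deProb),
        noiseScale = as.numeric(noiseScale),
        lambdaDropout = as.numeric(lambdaDropout), seed = as.integer(seed))
}

#' @rdname SimConfig-class
#' @param object a `SimConfig` object.
#' @export
setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d cells x %d genes, %d clusters (%s)\n",
                object@nCells, object@nGenes, object@nClusters,
                paste(object@clusterProps, collapse = "/")))
    cat(sprintf("  deProb=%.3g noiseScale=%.3g lambda=%.4g seed=%d\n",
                object@deProb, object@noiseScale, object@lambdaDropout,
                object@seed))
})

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Largest-remainder apportionment of cells to clusters
#'
#' @param nCells total number of cells.
#' @param props cluster proportions summing to 1.
#' @return Integer counts summing to `nCells`.
#' @keywords internal
.clusterCounts <- function(nCells, props) {
    quota <- nCells * props
    counts <- floor(quota)
    short <- nCells - sum(counts)
    if (short > 0) {
        ord <- order(quota - counts, decreasing = TRUE)
        counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
    }
    as.integer(counts)
}

#' Generate a cluster-structured ground-truth matrix
#'
#' Cells are assigned to clusters by largest-remainder rounding of the
#' cluster proportions. Per-gene base means are drawn once from a
#' log-normal distribution; each gene is marked differential with
#' probability `deProb` and, if so, receives cluster-specific log-normal
#' fold changes. Each cell's value is the cluster mean of its gene plus
#' Gaussian noise with standard deviation `noiseScale * V_g`, where the
#' replicate-level per-gene sd `V_g` combines a Poisson-like and a
#' multiplicative component (`0.25 * sqrt(mu_g) + 0.05 * mu_g`);
#' negative draws are clamped to 0. Fully deterministic given the
#' config seed.
#'
#' @param config a [SimConfig].
#'
#' @return A [SimTruth] whose `dropout` slot equals the truth and whose
#'   dropout mask is empty; apply [applyDropout()] (or use
#'   [simulateDropoutData()]) to introduce zeros.
#' @export
simulateTruth <- function(config) {
    validObject(config)
    n <- config@nCells; m <- config@nGenes; K <- config@nClusters
    counts <- .clusterCounts(n, config@clusterProps)
    labels <- rep.int(seq_len(K), counts)
    truth <- .withSeed(config@seed, {
        baseMean <- rlnorm(m, meanlog = 2, sdlog = 1)
        isDe <- runif(m) < config@deProb
        clusterMeans <- matrix(baseMean, K, m, byrow = TRUE)
        if (any(isDe)) {
            fc <- matrix(rlnorm(K * sum(isDe), meanlog = 0.1, sdlog = 0.4),
                         K, sum(isDe))
            clusterMeans[, isDe] <- clusterMeans[, isDe] * fc
        }
        Vg <- 0.25 * sqrt(baseMean) + 0.05 * baseMean
        noise <- matrix(rnorm(n * m, sd = 1), n, m) *
            matrix(config@noiseScale * Vg, n, m, byrow = TRUE)
        pmax(clusterMeans[labels, , drop = FALSE] + noise, 0)
    })
    dimnames(truth) <- list(paste0("cell", seq_len(n)),
                            paste0("gene", seq_len(m)))
    new("SimTruth", truth = truth, dropout = truth,
        maskDropped = matrix(logical(0), 0, 0), labels = labels,
        bulk = colMeans(truth), config = config)
}

#' Dropout probability of a gene
#'
#' The exponential dropout model: a gene with mean expression `mu` is
#' zeroed with probability `exp(-lambda * mu^2)`, so lowly expressed
#' genes drop out at high rates and strongly expressed genes survive.
#'
#' @param meanExpr non-negative mean expression (vectorised).
#' @param lambda non-negative rate parameter.
#'
#' @return Dropout probabilities in (0, 1].
#' @examples
#' dropoutProbability(c(0, 2), lambda = 0.1)
#' @export
dropoutProbability <- function(meanExpr, lambda) {
    if (any(!is.finite(meanExpr)) || any(meanExpr < 0))
        .sbiStop("sbiDomainError", "'meanExpr' must be finite and >= 0")
    if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
        .sbiStop("sbiDomainError", "'lambda' must be a single number >= 0")
    exp(-lambda * meanExpr^2)
}

#' Introduce Bernoulli dropout zeros
#'
#' For each gene, the dropout rate is computed from its mean expression
#' across cells via [dropoutProbability()]; every entry of that gene is
#' then zeroed independently with that probability. Deterministic given
#' the seed.
#'
#' @param truth non-negative numeric matrix (cells x genes) or
#'   [SimTruth].
#' @param lambda non-negative rate parameter.
#' @param seed integer seed for the Bernoulli draws.
#'
#' @return For a matrix input, a list with elements `dropout` (matrix
#'   with introduced zeros) and `mask` (logical matrix of Bernoulli
#'   hits). For a [SimTruth] input, the object with its `dropout`,
#'   `maskDropped` and config lambda slots filled in.
#' @export
applyDropout <- function(truth, lambda, seed = 1L) {
    if (is(truth, "SimTruth")) {
        res <- applyDropout(truth@truth, lambda, seed)
        cfg <- truth@config
        cfg@lambdaDropout <- as.numeric(lambda)
        return(new("SimTruth", truth = truth@truth, dropout = res$dropout,
                   maskDropped = res$mask, labels = truth@labels,
                   bulk = truth@bulk, config = cfg))
    }
    truth <- as.matrix(truth)
    if (any(truth < 0) || any(!is.finite(truth)))
        .sbiStop("sbiDomainError", "'truth' must be finite and >= 0")
    p <- dropoutProbability(colMeans(truth), lambda)
    mask <- .withSeed(seed, {
        u <- matrix(runif(length(truth)), nrow(truth))
        u < matrix(p, nrow(truth), ncol(truth), byrow = TRUE)
    })
    dropout <- truth
    dropout[mask] <- 0
    dimnames(mask) <- dimnames(truth)
    list(dropout = dropout, mask = mask)
}

#' Calibrate the dropout rate parameter to a target zero fraction
#'
#' Finds `lambda` such that the expected zero fraction of the dropout
#' matrix — pre-existing zeros plus the per-gene Bernoulli rates
#' `exp(-lambda * mean_g^2)` on the remaining entries — matches the
#' requested target. The expected fraction is monotone decreasing in
#' `lambda`, so a bisection suffices; the returned value matches the
#' target expectation to within 0.5 percentage points.
#'
#' @param truth non-negative matrix (cells x genes) or [SimTruth].
#' @param targetZeroFraction requested overall zero fraction in (0, 1).
#'
#' @return A single non-negative `lambda`.
#' @export
calibrateLambda <- function(truth, targetZeroFraction) {
    if (is(truth, "SimTruth")) truth <- truth@truth
    truth <- as.matrix(truth)
    if (targetZeroFraction <= 0 || targetZeroFraction >= 1)
        .sbiStop("sbiDomainError", "'targetZeroFraction' must be in (0, 1)")
    mu <- colMeans(truth)
    zfrac <- colMeans(truth == 0)
    expectedZero <- function(lam)
        mean(zfrac + (1 - zfrac) * dropoutProbability(mu, lam))
    intrinsic <- mean(truth == 0)
    if (targetZeroFraction <= intrinsic)
        .sbiStop("sbiInfeasibleTargetError", sprintf(
            "target zero fraction %.3f is below the matrix's intrinsic zero fraction %.3f",
            targetZeroFraction, intrinsic))
    lo <- 0
    hi <- 1
    while (expectedZero(hi) > targetZeroFraction && hi < 1e12) hi <- hi * 2
    for (i in seq_len(200)) {
        mid <- (lo + hi) / 2
        if (expectedZero(mid) > targetZeroFraction) lo <- mid else hi <- mid
        if (abs(expectedZero(mid) - targetZeroFraction) < 5e-4) return(mid)
    }
    (lo + hi) / 2
}

#' Per-gene bulk averages of a truth matrix
#'
#' The matched bulk profile of a simulation is the vector of per-gene
#' arithmetic means of the dropout-free truth across cells.
#'
#' @param truth non-negative matrix (cells x genes) or [SimTruth].
#'
#' @return A [BulkVector].
#' @examples
#' bulkFromTruth(matrix(1:4, 2))
#' @export
bulkFromTruth <- function(truth) {
    if (is(truth, "SimTruth")) truth <- truth@truth
    truth <- as.matrix(truth)
    BulkVector(colMeans(truth),
               colnames(truth) %||% paste0("gene", seq_len(ncol(truth))))
}

#' Run the full dropout simulation
#'
#' Generates the cluster-structured truth ([simulateTruth()]),
#' optionally calibrates the dropout parameter to a target zero fraction
#' ([calibrateLambda()]), introduces Bernoulli dropout zeros
#' ([applyDropout()], seeded at `config seed + 1`), and attaches the
#' matched bulk vector (per-gene means of the truth).
#'
#' @param config a [SimConfig].
#' @param targetZeroFraction optional overall zero fraction in (0, 1);
#'   overrides the config's `lambdaDropout`.
#'
#' @return A complete [SimTruth].
#' @examples
#' sim <- simulateDropoutData(simConfig(nCells = 60, nGenes = 80, seed = 3),
#'                            targetZeroFraction = 0.6)
#' sim
#' @export
simulateDropoutData <- function(config, targetZeroFraction = NULL) {
    sim <- simulateTruth(config)
    lam <- if (is.null(targetZeroFraction)) config@lambdaDropout
           else calibrateLambda(sim@truth, targetZeroFraction)
    applyDropout(sim, lam, seed = config@seed + 1L)
}
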