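.asMat <- function(x) {
    if (is(x, "ScMatrix")) exprValues(x)
    else if (is(x, "ImputeResult")) exprValues(imputedMatrix(x))
    else as.matrix(x)
}

#' Imputation error
#'
#' The entrywise L2 (Frobenius) norm of the difference between the
#' imputed and the true matrix, the primary accuracy measure for
#' benchmarks with known ground truth. The spectral (operator-2) norm
#' is available behind `norm = "spectral"`.
#'
#' @param imputed,truth matrices of identical shape (or [ScMatrix]).
#' @param norm `"frobenius"` (default) or `"spectral"`.
#'
#' @return A single non-negative number.
#' @examples
#' imputationError(matrix(c(4, 0, 0, 5), 2), matrix(c(1, 0, 0, 1), 2))
#' @export
imputationError <- function(imputed, truth,
                            norm = c("frobenius", "spectral")) {
    norm <- match.arg(norm)
    imputed <- .asMat(imputed); truth <- .asMat(truth)
    .checkSameDim(imputed, truth, "'imputed' and 'truth'")
    diff <- imputed - truth
    if (norm == "frobenius") sqrt(sum(diff^2))
    else svd(diff, nu = 0, nv = 0)$d[1L]
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum absolute difference between the empirical distribution
#' functions of two samples, used to quantify how well an imputed
#' expression distribution matches the true one. Only the D statistic is
#' returned; ties are unproblematic for D itself.
#'
#' @param sampleA,sampleB non-empty numeric vectors.
#' @param log1pTransform apply `log1p` to both samples first (the usual
#'   scale for expression distribution comparisons; default `FALSE` so
#'   the statistic is computed on the values as given).
#'
#' @return D in \[0, 1\].
#' @examples
#' ksStatistic(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
ksStatistic <- function(sampleA, sampleB, log1pTransform = FALSE) {
    sampleA <- as.numeric(sampleA); sampleB <- as.numeric(sampleB)
    if (length(sampleA) == 0L || length(sampleB) == 0L)
        .sbiStop("sbiDomainError", "samples must be non-empty")
    if (log1pTransform) {
        sampleA <- log1p(sampleA); sampleB <- log1p(sampleB)
    }
    unname(suppressWarnings(
        ks.test(sampleA, sampleB, exact = FALSE)$statistic))
}

.corUpper <- function(mat, axis) {
    items <- if (axis == "cells") t(mat) else mat
    # cor() correlates columns; pass items as columns
    cm <- suppressWarnings(cor(items))
    cm[upper.tri(cm)]
}

#' Preservation of the correlation structure
#'
#' Computes the Pearson correlation matrix across cells (or genes) for
#' the true matrix and for a second matrix (dropout or imputed),
#' vectorises the strict upper triangles, and returns the Pearson
#' correlation between the two vectors. Values near 1 mean the pairwise
#' relationship structure of the truth survived. Pairs whose correlation
#' is undefined in either matrix (zero-variance items) are dropped, with
#' a message reporting how many.
#'
#' @param truth,other matrices of identical shape (or [ScMatrix]).
#' @param axis `"cells"` or `"genes"`: which pairwise correlation
#'   matrix to compare.
#'
#' @return A number in \[-1, 1\].
#' @export
correlationPreservation <- function(truth, other,
                                    axis = c("cells", "genes")) {
    axis <- match.arg(axis)
    truth <- .asMat(truth); other <- .asMat(other)
    .checkSameDim(truth, other, "'truth' and 'other'")
    nItems <- if (axis == "cells") nrow(truth) else ncol(truth)
    if (nItems < 3L)
        .sbiStop("sbiDomainError",
                 sprintf("need at least 3 %s to compare correlations", axis))
    ut <- .corUpper(truth, axis)
    uo <- .corUpper(other, axis)
    ok <- is.finite(ut) & is.finite(uo)
    if (!all(ok))
        message(sum(!ok), " correlation pairs undefined and dropped")
    if (sum(ok) < 2L || sd(ut[ok]) == 0 || sd(uo[ok]) == 0)
        .sbiStop("sbiDomainError",
                 "not enough defined, varying correlation pairs")
    cor(ut[ok], uo[ok])
}

.pairCors <- function(mat, labels, what = c("within", "between")) {
    # cell-cell Pearson correlations pooled by label agreement
    cm <- suppressWarnings(cor(t(mat)))
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    vals <- cm[upper.tri(cm)]
    same <- labels[idx[, 1L]] == labels[idx[, 2L]]
    ok <- is.finite(vals)
    list(within = vals[same & ok], between = vals[!same & ok])
}

.markerGenes <- function(mat, labels, k) {
    # between-cluster over within-cluster variance ratio, top-k genes
    groups <- split(seq_len(nrow(mat)), labels)
    grandMean <- colMeans(mat)
    between <- numeric(ncol(mat)); within <- numeric(ncol(mat))
    for (g in groups) {
        mu <- colMeans(mat[g, , drop = FALSE])
        between <- between + length(g) * (mu - grandMean)^2
        within <- within +
            colSums((mat[g, , drop = FALSE] -
                     matrix(mu, length(g), ncol(mat), byrow = TRUE))^2)
    }
    ratio <- between / pmax(within, .Machine$double.eps)
    whichMarker <- order(ratio, decreasing = TRUE)[seq_len(min(k, ncol(mat)))]
    markerCluster <- integer(length(whichMarker))
    for (i in seq_along(whichMarker)) {
        mus <- vapply(groups, function(g)
            mean(mat[g, whichMarker[i]]), numeric(1))
        markerCluster[i] <- which.max(mus)
    }
    list(genes = whichMarker, cluster = markerCluster)
}

#' Cluster-stratified correlation distortion
#'
#' Measures how much imputation distorts the cluster structure. In
#' `"cell"` mode, for each matrix the within-cluster and between-cluster
#' cell-cell Pearson correlations are pooled and compared by the
#' two-sample KS statistic; the distortion is the absolute difference
#' between the KS statistic of the truth and that of the imputed matrix
#' (0 means the separation between within- and between-cluster
#' correlation distributions is perfectly preserved). In
#' `"gene_marker"` mode the same comparison is made on gene-gene
#' correlations, stratified into pairs of marker genes of the same
#' cluster versus pairs of markers of different clusters; markers are
#' user-supplied or derived as the top `nMarkers` genes by
#' between/within-cluster variance ratio (reported via a message).
#'
#' @param truth,imputed matrices of identical shape (or [ScMatrix]).
#' @param labels cluster label per cell (at least 2 clusters).
#' @param mode `"cell"` or `"gene_marker"`.
#' @param markers optional integer or character vector of marker genes
#'   (gene_marker mode); derived from `truth` when absent.
#' @param nMarkers number of markers derived per matrix when `markers`
#'   is absent (default 50).
#'
#' @return Non-negative distortion `|KS_truth - KS_imputed|`.
#' @export
clusterDistortion <- function(truth, imputed, labels,
                              mode = c("cell", "gene_marker"),
                              markers = NULL, nMarkers = 50L) {
    mode <- match.arg(mode)
    truth <- .asMat(truth); imputed <- .asMat(imputed)
    .checkSameDim(truth, imputed, "'truth' and 'imputed'")
    labels <- as.integer(factor(labels))
    if (length(labels) != nrow(truth))
        .sbiStop("sbiDomainError", "'labels' must cover all cells")
    if (length(unique(labels)) < 2L)
        .sbiStop("sbiDomainError", "need at least 2 clusters")
    if (all(tabulate(labels) < 2L))
        .sbiStop("sbiDomainError", "all clusters are singletons")
    ksOf <- function(mat) {
        if (mode == "cell") {
            pc <- .pairCors(mat, labels)
            ksStatistic(pc$within, pc$between)
        } else {
            if (is.null(markers)) {
                mk <- .markerGenes(truth, labels, nMarkers)
                message("derived ", length(mk$genes),
                        " marker genes by between/within variance ratio")
            } else {
                genes <- if (is.character(markers))
                    match(markers, colnames(truth)) else as.integer(markers)
                genes <- genes[!is.na(genes)]
                mus <- vapply(split(seq_len(nrow(truth)), labels),
                              function(g) colMeans(truth[g, genes,
                                                         drop = FALSE]),
                              numeric(length(genes)))
                mk <- list(genes = genes,
                           cluster = max.col(matrix(mus,
                                                    length(genes))))
            }
            markers <<- mk$genes
            sub <- mat[, mk$genes, drop = FALSE]
            cm <- suppressWarnings(cor(sub))
            idx <- which(upper.tri(cm), arr.ind = TRUE)
            vals <- cm[upper.tri(cm)]
            same <- mk$cluster[idx[, 1L]] == mk$cluster[idx[, 2L]]
            ok <- is.finite(vals)
            if (!any(same & ok) || !any(!same & ok))
                .sbiStop("sbiDomainError",
                         "marker stratification produced an empty group")
            ksStatistic(vals[same & ok], vals[!same & ok])
        }
    }
    ksT <- ksOf(truth)
    ksI <- ksOf(imputed)
    abs(ksT - ksI)
}

.meanAbsPairCor <- function(mat, cols, absolute) {
    cm <- suppressWarnings(cor(mat[, cols, drop = FALSE]))
    v <- cm[upper.tri(cm)]
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NA_real_)
    if (absolute) mean(abs(v)) else mean(v)
}

#' Pathway gene correlation score (PGCS)
#'
#' The mean absolute pairwise Pearson correlation among the pathway's
#' genes minus the average of the same statistic over `nRandom` random
#' gene sets of identical size drawn from the non-pathway genes. A
#' positive score means pathway genes are more strongly co-expressed
#' than size-matched random sets. The absolute value captures
#' co-regulation of either sign; set `absolute = FALSE` for the signed
#' mean.
#'
#' @param mat expression matrix (cells x genes) or [ScMatrix]; gene
#'   columns must be named for character pathways.
#' @param pathway a [PathwaySet] (or character vector of gene names).
#' @param nRandom number of random background sets (default 100).
#' @param seed integer seed for the background draws.
#' @param absolute use absolute correlations (default `TRUE`).
#'
#' @return The score, or `NA` (with a warning) if fewer than 2 pathway
#'   genes map into the matrix.
#' @export
pgcs <- function(mat, pathway, nRandom = 100L, seed = 1L, absolute = TRUE) {
    mat <- .asMat(mat)
    genes <- if (is(pathway, "PathwaySet")) pathway@genes
             else as.character(pathway)
    cols <- match(genes, colnames(mat))
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2L) {
        warning("pathway maps to fewer than 2 genes; skipping")
        return(NA_real_)
    }
    bg <- setdiff(seq_len(ncol(mat)), cols)
    if (length(bg) < length(cols))
        .sbiStop("sbiDomainError",
                 "not enough non-pathway genes to draw background sets")
    draws <- .pgcsDraws(bg, length(cols), nRandom, seed)
    own <- .meanAbsPairCor(mat, cols, absolute)
    null <- vapply(draws, function(cl) .meanAbsPairCor(mat, cl, absolute),
                   numeric(1))
    own - mean(null, na.rm = TRUE)
}

.pgcsDraws <- function(bg, size, nRandom, seed) {
    .withSeed(seed, lapply(seq_len(nRandom),
                           function(i) sample(bg, size)))
}

#' Change in PGCS from imputation
#'
#' `pgcs(imputed) - pgcs(raw)` with the random background gene sets
#' shared between the two evaluations (a paired design), so the
#' difference reflects the matrices and not the draws. Antisymmetric in
#' its two matrix arguments.
#'
#' @param imputed,raw matrices of identical shape with the same gene
#'   columns.
#' @inheritParams pgcs
#'
#' @return The paired difference, or `NA` if the pathway does not map.
#' @export
deltaPgcs <- function(imputed, raw, pathway, nRandom = 100L, seed = 1L,
                      absolute = TRUE) {
    imputed <- .asMat(imputed); raw <- .asMat(raw)
    .checkSameDim(imputed, raw, "'imputed' and 'raw'")
    pgcs(imputed, pathway, nRandom, seed, absolute) -
        pgcs(raw, pathway, nRandom, seed, absolute)
}

#' Dunn index of a clustering
#'
#' The classic cluster-separation ratio: the minimal distance between
#' points of different clusters (single linkage), divided by the
#' maximal within-cluster diameter (complete diameter), on Euclidean
#' distances. Higher is better; the index is invariant under isometries
#' and positive scaling. If every cluster has zero diameter the ratio is
#' `Inf`.
#'
#' @param data numeric matrix of observations in rows (an expression
#'   matrix or a low-dimensional embedding).
#' @param labels cluster label per row; at least 2 non-empty clusters.
#'
#' @return A positive number (possibly `Inf`).
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' dunnIndex(pts, c(1, 1, 2, 2))
#' @export
dunnIndex <- function(data, labels) {
    data <- .asMat(data)
    labels <- as.integer(factor(labels))
    if (length(labels) != nrow(data))
        .sbiStop("sbiDomainError", "'labels' must cover all rows")
    if (length(unique(labels)) < 2L)
        .sbiStop("sbiDomainError", "need at least 2 clusters")
    dm <- as.matrix(dist(data))
    same <- outer(labels, labels, "==")
    diag(same) <- NA
    interMin <- min(dm[!same & !is.na(same)])
    intraMax <- max(c(0, dm[same & !is.na(same)]))
    if (intraMax == 0) return(Inf)
    interMin / intraMax
}

#' Assemble an evaluation report
#'
#' Runs the evaluation metrics that apply to the supplied inputs and
#' returns a named list suitable for JSON serialisation: imputation
#' error of the imputed (and, when given, dropout) matrix, KS agreement
#' of the pooled expression distributions, cell- and gene-axis
#' correlation preservation, cluster distortion when labels are given,
#' and per-pathway PGCS / delta-PGCS when pathways are given.
#'
#' @param truth ground-truth matrix.
#' @param imputed imputed matrix.
#' @param dropout optional raw dropout matrix.
#' @param labels optional cluster labels.
#' @param pathways optional list of [PathwaySet] objects.
#' @param nRandom,seed background-draw controls for PGCS.
#'
#' @return A named list of finite scalars (and per-pathway tables).
#' @export
evaluateImputation <- function(truth, imputed, dropout = NULL,
                               labels = NULL, pathways = NULL,
                               nRandom = 100L, seed = 1L) {
    truth <- .asMat(truth); imputed <- .asMat(imputed)
    rep <- list(imputationError = imputationError(imputed, truth),
                ksStatistic = ksStatistic(as.numeric(truth),
                                          as.numeric(imputed),
                                          log1pTransform = TRUE),
                cellCorrelationPreservation =
                    correlationPreservation(truth, imputed, "cells"),
                geneCorrelationPreservation =
                    correlationPreservation(truth, imputed, "genes"))
    if (!is.null(dropout)) {
        dropout <- .asMat(dropout)
        rep$dropoutError <- imputationError(dropout, truth)
        rep$dropoutCellCorrelationPreservation <-
            correlationPreservation(truth, dropout, "cells")
    }
    if (!is.null(labels)) {
        rep$clusterDistortion <-
            clusterDistortion(truth, imputed, labels, mode = "cell")
        rep$dunnIndexImputed <- dunnIndex(imputed, labels)
        rep$dunnIndexTruth <- dunnIndex(truth, labels)
    }
    if (!is.null(pathways)) {
        if (is(pathways, "PathwaySet")) pathways <- list(pathways)
        raw <- if (is.null(dropout)) truth else dropout
        tab <- lapply(pathways, function(p) {
            list(name = p@name,
                 pgcsImputed = pgcs(imputed, p, nRandom, seed),
                 deltaPgcs = deltaPgcs(imputed, raw, p, nRandom, seed))
        })
        rep$pathways <- tab
    }
    rep
}
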