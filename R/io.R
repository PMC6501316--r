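.detectFormat <- function(path) {
    ext <- tolower(tools::file_ext(path))
    switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
           .sbiStop("sbiFormatError",
                    sprintf("cannot infer format from extension '%s'", ext)))
}

#' Read an expression matrix
#'
#' Reads a dense CSV/TSV (header row of names, first column of index
#' names) or a Matrix Market `.mtx` file with companion `genes.tsv` and
#' `barcodes.tsv` files in the same directory, and returns an
#' [ScMatrix] in cells x genes orientation regardless of the on-disk
#' layout. For Matrix Market input the on-disk orientation defaults to
#' genes in rows (the common sparse convention), for dense input to
#' cells in rows; pass `genesInRows` explicitly when the file differs.
#'
#' @param path path to the matrix file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param genesInRows logical; is the on-disk layout genes x cells?
#'   Defaults to `TRUE` for mtx and `FALSE` otherwise.
#' @param genesFile,cellsFile companion name files for mtx input;
#'   default `genes.tsv` / `barcodes.tsv` next to the matrix.
#'
#' @return An [ScMatrix].
#' @export
readExpression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                           genesInRows = NULL, genesFile = NULL,
                           cellsFile = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        .sbiStop("sbiIOError", sprintf("file not found: %s", path))
    if (format == "auto") format <- .detectFormat(path)
    if (format == "mtx") {
        if (is.null(genesInRows)) genesInRows <- TRUE
        dir <- dirname(path)
        genesFile <- genesFile %||% file.path(dir, "genes.tsv")
        cellsFile <- cellsFile %||% file.path(dir, "barcodes.tsv")
        for (f in c(genesFile, cellsFile))
            if (!file.exists(f))
                .sbiStop("sbiIOError", sprintf("companion file not found: %s", f))
        m <- as.matrix(Matrix::readMM(path))
        rowNamesV <- read.table(genesFile, sep = "\t",
                                stringsAsFactors = FALSE)[[1L]]
        colNamesV <- read.table(cellsFile, sep = "\t",
                                stringsAsFactors = FALSE)[[1L]]
        if (genesInRows) {
            if (length(rowNamesV) != nrow(m) || length(colNamesV) != ncol(m))
                .sbiStop("sbiIOError", "name files do not match matrix dimensions")
            m <- t(m)
            geneN <- rowNamesV; cellN <- colNamesV
        } else {
            if (length(rowNamesV) != ncol(m) || length(colNamesV) != nrow(m))
                .sbiStop("sbiIOError", "name files do not match matrix dimensions")
            geneN <- rowNamesV; cellN <- colNamesV
        }
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- tryCatch(
            read.table(path, header = TRUE, sep = sep, row.names = 1L,
                       check.names = FALSE, stringsAsFactors = FALSE),
            error = function(e) .sbiStop("sbiIOError", sprintf(
                "failed to parse %s: %s", path, conditionMessage(e))))
        m <- as.matrix(df)
        if (!is.numeric(m))
            .sbiStop("sbiIOError", "matrix contains non-numeric entries")
        if (is.null(genesInRows)) genesInRows <- FALSE
        if (genesInRows) m <- t(m)
        geneN <- colnames(m); cellN <- rownames(m)
    }
    if (anyDuplicated(geneN))
        .sbiStop("sbiIOError", paste0("duplicate gene names: ",
                 paste(head(unique(geneN[duplicated(geneN)]), 5L),
                       collapse = ", ")))
    if (any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1L, ]
        .sbiStop("sbiIOError", sprintf(
            "negative entry at cell %s, gene %s", bad[1L], bad[2L]))
    }
    ScMatrix(m, geneNames = geneN, cellNames = cellN)
}

#' Write an expression matrix
#'
#' Writes dense CSV/TSV (values rounded to `digits` significant digits)
#' or an exact Matrix Market triplet (`.mtx` plus `genes.tsv` and
#' `barcodes.tsv` alongside).
#'
#' @param x an [ScMatrix] or numeric matrix (cells x genes).
#' @param path output path; extension selects the format unless given.
#' @param format `"auto"`, `"csv"`, `"tsv"` or `"mtx"`.
#' @param genesInRows write the dense file transposed (genes x cells).
#' @param digits significant digits for dense output (default 6).
#'
#' @return Invisibly, the path written.
#' @export
writeExpression <- function(x, path, format = c("auto", "csv", "tsv", "mtx"),
                            genesInRows = FALSE, digits = 6L) {
    format <- match.arg(format)
    if (format == "auto") format <- .detectFormat(path)
    if (!is(x, "ScMatrix")) x <- ScMatrix(x)
    m <- exprValues(x)
    if (format == "mtx") {
        Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE), path)
        dir <- dirname(path)
        writeLines(geneNames(x), file.path(dir, "genes.tsv"))
        writeLines(cellNames(x), file.path(dir, "barcodes.tsv"))
    } else {
        sep <- if (format == "csv") "," else "\t"
        out <- if (genesInRows) t(m) else m
        df <- as.data.frame(signif(out, digits), check.names = FALSE)
        write.table(df, path, sep = sep, quote = FALSE,
                    col.names = NA, row.names = TRUE)
    }
    invisible(path)
}

#' Read a bulk expression table
#'
#' Two-column TSV (gene, value); an optional header line is detected
#' and skipped.
#'
#' @param path path to the TSV file.
#' @return A named numeric vector of per-gene bulk values.
#' @export
readBulk <- function(path) {
    if (!file.exists(path))
        .sbiStop("sbiIOError", sprintf("file not found: %s", path))
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        .sbiStop("sbiIOError", "bulk table must have two columns (gene, value)")
    if (is.character(df[[2L]]) && is.na(suppressWarnings(as.numeric(df[1L, 2L]))))
        df <- df[-1L, , drop = FALSE]
    vals <- suppressWarnings(as.numeric(df[[2L]]))
    if (any(is.na(vals)))
        .sbiStop("sbiIOError", "non-numeric bulk values")
    setNames(vals, as.character(df[[1L]]))
}

#' Align a bulk profile to a single-cell matrix
#'
#' Reorders the bulk values into the matrix's gene order. Without
#' `intersect`, every matrix gene must be present in the bulk table and
#' any miss is an error naming the offending genes; with `intersect`,
#' both objects are restricted to the shared genes (order taken from
#' the matrix) and the number of dropped genes is reported via a
#' message.
#'
#' @param sc an [ScMatrix].
#' @param bulkTable a named numeric vector (gene -> value), a
#'   [BulkVector], or a two-column data frame.
#' @param intersect restrict to the gene intersection instead of
#'   erroring on misses.
#'
#' @return A list with elements `sc` ([ScMatrix]) and `bulk`
#'   ([BulkVector]) over identical, identically ordered genes.
#' @export
alignBulk <- function(sc, bulkTable, intersect = FALSE) {
    if (is(bulkTable, "BulkVector"))
        bulkTable <- setNames(bulkTable@values, bulkTable@geneNames)
    if (is.data.frame(bulkTable))
        bulkTable <- setNames(as.numeric(bulkTable[[2L]]),
                              as.character(bulkTable[[1L]]))
    if (anyDuplicated(names(bulkTable)))
        .sbiStop("sbiAlignmentError", paste0(
            "duplicate genes in bulk table: ",
            paste(head(unique(names(bulkTable)[duplicated(names(bulkTable))]),
                       5L), collapse = ", ")))
    scGenes <- geneNames(sc)
    shared <- intersect(scGenes, names(bulkTable))
    if (length(shared) == 0L)
        .sbiStop("sbiAlignmentError",
                 "no genes shared between matrix and bulk table")
    if (!intersect) {
        missing <- setdiff(scGenes, names(bulkTable))
        if (length(missing))
            .sbiStop("sbiAlignmentError", paste0(
                "bulk table is missing matrix genes: ",
                paste(head(missing, 10L), collapse = ", ")))
        keep <- scGenes
    } else {
        keep <- scGenes[scGenes %in% shared]
        nDropped <- length(scGenes) - length(keep)
        if (nDropped > 0L)
            message("restricting to ", length(keep), " shared genes (",
                    nDropped, " matrix genes dropped)")
    }
    scOut <- ScMatrix(exprValues(sc)[, keep, drop = FALSE],
                      geneNames = keep, cellNames = cellNames(sc))
    list(sc = scOut, bulk = BulkVector(unname(bulkTable[keep]), keep))
}

#' Read a GMT pathway file
#'
#' One pathway per line: name, tab, description, tab, tab-separated
#' gene symbols. Pathways with fewer than 2 genes are skipped with a
#' warning.
#'
#' @param path path to the GMT file.
#' @return A list of [PathwaySet] objects.
#' @export
readPathways <- function(path) {
    if (!file.exists(path))
        .sbiStop("sbiIOError", sprintf("file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        genes <- unique(parts[-c(1L, 2L)])
        genes <- genes[nzchar(genes)]
        if (length(parts) < 4L || length(genes) < 2L) {
            warning("skipping pathway '", parts[1L],
                    "': fewer than 2 genes")
            next
        }
        out[[parts[1L]]] <- pathwaySet(parts[1L], genes, parts[2L])
    }
    out
}

#' Write run diagnostics as JSON
#'
#' Serialises parameters, seeds, package version, input checksums and
#' the solver traces of an [ImputeResult].
#'
#' @param result an [ImputeResult].
#' @param path output JSON path.
#' @param inputs optional named character vector of input file paths to
#'   checksum.
#' @param seed optional seed to record.
#'
#' @return Invisibly, the path written.
#' @export
writeDiagnostics <- function(result, path, inputs = NULL, seed = NULL) {
    st <- admmState(result)
    p <- result@params
    diag <- list(
        package = "scBulkImpute",
        version = as.character(utils::packageVersion("scBulkImpute")),
        params = list(alpha = p@alpha, beta = p@beta, gamma = p@gamma,
                      maxIter = p@maxIter, tol = p@tol,
                      innerMaxIter = p@innerMaxIter, innerTol = p@innerTol),
        iterations = st@k,
        converged = st@converged,
        primalResiduals = st@primalResiduals,
        objectiveTrace = st@objectiveTrace)
    if (!is.null(seed)) diag$seed <- seed
    if (!is.null(inputs)) {
        sums <- tools::md5sum(inputs)
        diag$inputChecksums <- as.list(setNames(unname(sums),
                                                basename(inputs)))
    }
    jsonlite::write_json(diag, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read or write a flat run configuration
#'
#' Round-trippable YAML serialisation of a flat key-value run
#' configuration (model parameters, IO options, seed, paths).
#'
#' @param config a flat named list.
#' @param path YAML path.
#' @return `writeRunConfig` returns the path invisibly; `readRunConfig`
#'   returns the named list.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(is.list(config))
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        .sbiStop("sbiIOError", sprintf("file not found: %s", path))
    yaml::read_yaml(path)
}
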