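#' Load a counts matrix
#'
#' Reads Matrix Market (\code{.mtx} with \code{genes.tsv} /
#' \code{barcodes.tsv} sidecars in the same directory) or dense TSV/CSV
#' (genes as rows, first column gene ids, header row of sample/cell ids).
#' The dialect is inferred from the extension when not given.
#'
#' @param path file path.
#' @param dialect \code{"mtx"}, \code{"tsv"} or \code{"csv"}; inferred from
#'   the extension when NULL.
#' @param genesFile,barcodesFile sidecar paths for mtx input (defaults:
#'   \code{genes.tsv} / \code{barcodes.tsv} next to the matrix).
#' @return Numeric matrix with gene ids as rownames and sample/cell ids as
#'   colnames.
#' @export
loadCounts <- function(path, dialect = NULL, genesFile = NULL,
                       barcodesFile = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(dialect)) {
        ext <- tolower(tools::file_ext(path))
        dialect <- switch(ext, mtx = "mtx", tsv = "tsv", txt = "tsv",
                          csv = "csv",
                          stop("cannot infer dialect from extension '.",
                               ext, "'"))
    }
    if (dialect == "mtx") {
        m <- Matrix::readMM(path)
        if (is.null(genesFile))
            genesFile <- file.path(dirname(path), "genes.tsv")
        if (is.null(barcodesFile))
            barcodesFile <- file.path(dirname(path), "barcodes.tsv")
        if (!file.exists(genesFile))
            stop("missing gene sidecar: ", genesFile)
        if (!file.exists(barcodesFile))
            stop("missing barcode sidecar: ", barcodesFile)
        genes <- read.delim(genesFile, header = FALSE,
                            stringsAsFactors = FALSE)[, 1]
        cells <- read.delim(barcodesFile, header = FALSE,
                            stringsAsFactors = FALSE)[, 1]
        if (length(genes) != nrow(m))
            stop("gene sidecar length does not match the matrix")
        if (length(cells) != ncol(m))
            stop("barcode sidecar length does not match the matrix")
        m <- as.matrix(m)
        dimnames(m) <- list(genes, cells)
    } else {
        sep <- if (dialect == "csv") "," else "\t"
        df <- read.delim(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
        genes <- as.character(df[, 1])
        m <- as.matrix(df[, -1, drop = FALSE])
        storage.mode(m) <- "double"
        rownames(m) <- genes
    }
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    if (length(dup))
        stop("duplicated gene ids: ", paste(head(dup, 10), collapse = ", "))
    if (anyNA(m)) stop("counts contain missing values")
    if (min(m) < 0) stop("counts contain negative entries")
    m
}

#' Write a counts matrix
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path output path; \code{.mtx} writes Matrix Market plus
#'   \code{genes.tsv} / \code{barcodes.tsv} sidecars, anything else a dense
#'   TSV (or CSV for \code{.csv}).
#' @export
writeCounts <- function(counts, path) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "mtx") {
        Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
        write.table(rownames(counts),
                    file.path(dirname(path), "genes.tsv"),
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        write.table(colnames(counts),
                    file.path(dirname(path), "barcodes.tsv"),
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else {
        sep <- if (ext == "csv") "," else "\t"
        df <- data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE)
        write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Load cell annotations
#'
#' TSV with required columns \code{cell_id} and \code{cell_type}, optional
#' \code{subject}; extra columns are ignored with a message. Every cell id
#' in \code{cellIds} must be annotated (no silent dropping).
#'
#' @param path annotation TSV.
#' @param cellIds optional cell ids (e.g. colnames of the counts) the
#'   annotations must cover and get aligned to.
#' @return data.frame with columns cell_id, cell_type and, when present,
#'   subject; aligned to \code{cellIds} when given.
#' @export
loadAnnotations <- function(path, cellIds = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("cell_id", "cell_type")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(colnames(df), c(need, "subject"))
    if (length(extra))
        message("ignoring extra annotation columns: ",
                paste(extra, collapse = ", "))
    keep <- intersect(c(need, "subject"), colnames(df))
    df <- df[, keep, drop = FALSE]
    if (!is.null(cellIds)) {
        absent <- setdiff(cellIds, df$cell_id)
        if (length(absent))
            stop("cells present in counts but missing from annotations: ",
                 paste(head(absent, 10), collapse = ", "),
                 if (length(absent) > 10) sprintf(" (+%d more)",
                                                  length(absent) - 10))
        df <- df[match(cellIds, df$cell_id), , drop = FALSE]
        rownames(df) <- NULL
    }
    df
}

#' Load a single-cell reference from files
#'
#' Convenience wrapper around [loadCounts()] and [loadAnnotations()].
#'
#' @param countsPath counts file (mtx/tsv/csv).
#' @param annotationsPath annotation TSV.
#' @param ... passed to [loadCounts()].
#' @return A [ScReference-class].
#' @export
loadScReference <- function(countsPath, annotationsPath, ...) {
    cnt <- loadCounts(countsPath, ...)
    ann <- loadAnnotations(annotationsPath, cellIds = colnames(cnt))
    ScReference(cnt, cellType = ann$cell_type, subject = ann$subject)
}

.bundleTables <- c("mu", "var", "dispersion", "success_prob",
                   "specificity_weights", "fit_flags")

#' Save a reference panel as an on-disk bundle
#'
#' Writes a directory with \code{metadata.json}, \code{genes.tsv},
#' \code{cell_types.tsv} and one TSV per numeric table, all numeric values
#' at 17 significant digits so that load/save round-trips are bit-exact.
#'
#' @param panel a [ReferencePanel-class].
#' @param dir bundle directory (created; must not already contain a bundle
#'   unless \code{overwrite = TRUE}).
#' @param weights optional [CrossSampleWeights-class] persisted alongside.
#' @param overwrite logical.
#' @return The bundle directory, invisibly.
#' @export
saveReference <- function(panel, dir, weights = NULL, overwrite = FALSE) {
    if (file.exists(file.path(dir, "metadata.json")) && !overwrite)
        stop("bundle already exists at ", dir,
             " (use overwrite = TRUE)")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(list(schema_version = .BUNDLE_SCHEMA_VERSION,
                   gene_mode = panel@geneMode,
                   n_genes = length(panel@genes),
                   cell_types = panel@cellTypes),
              panel@metadata[setdiff(names(panel@metadata),
                                     "schema_version")])
    jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(panel@genes, file.path(dir, "genes.tsv"))
    writeLines(panel@cellTypes, file.path(dir, "cell_types.tsv"))
    writeNumTable <- function(m, file) {
        fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
        df <- data.frame(gene_id = panel@genes, fm)
        colnames(df) <- c("gene_id", panel@cellTypes)
        write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    writeNumTable(panel@mu, "mu.tsv")
    writeNumTable(panel@var, "var.tsv")
    writeNumTable(panel@dispersion, "dispersion.tsv")
    writeNumTable(panel@successProb, "success_prob.tsv")
    ff <- data.frame(gene_id = panel@genes, panel@fitFlag)
    colnames(ff) <- c("gene_id", panel@cellTypes)
    write.table(ff, file.path(dir, "fit_flags.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sw <- data.frame(gene_id = panel@genes,
                     w_s = sprintf("%.17g", panel@specificityWeight))
    write.table(sw, file.path(dir, "specificity_weights.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(weights))
        writeCrossSampleWeights(weights,
                                file.path(dir, "cross_sample_weights.tsv"))
    invisible(dir)
}

#' Load a reference panel bundle
#'
#' @param dir bundle directory written by [saveReference()].
#' @return A [ReferencePanel-class].
#' @export
loadReference <- function(dir) {
    metaPath <- file.path(dir, "metadata.json")
    if (!file.exists(metaPath)) stop("not a reference bundle: ", dir)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!identical(as.character(meta$schema_version),
                   .BUNDLE_SCHEMA_VERSION))
        stop("bundle schema version '", meta$schema_version,
             "' is not supported (expected ", .BUNDLE_SCHEMA_VERSION,
             "); migrate the bundle")
    needed <- c("genes.tsv", "cell_types.tsv", "mu.tsv", "var.tsv",
                "dispersion.tsv", "success_prob.tsv",
                "specificity_weights.tsv", "fit_flags.tsv")
    absent <- needed[!file.exists(file.path(dir, needed))]
    if (length(absent))
        stop("bundle is missing table(s): ", paste(absent, collapse = ", "))
    genes <- readLines(file.path(dir, "genes.tsv"))
    types <- readLines(file.path(dir, "cell_types.tsv"))
    readNumTable <- function(file) {
        df <- read.delim(file.path(dir, file), check.names = FALSE,
                         colClasses = "character")
        m <- matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])),
                    nrow(df), ncol(df) - 1,
                    dimnames = list(df[, 1], colnames(df)[-1]))
        m
    }
    mu <- readNumTable("mu.tsv")
    vv <- readNumTable("var.tsv")
    lam <- readNumTable("dispersion.tsv")
    pp <- readNumTable("success_prob.tsv")
    ffdf <- read.delim(file.path(dir, "fit_flags.tsv"),
                       check.names = FALSE, colClasses = "character")
    ff <- as.matrix(ffdf[, -1, drop = FALSE])
    dimnames(ff) <- dimnames(mu)
    sw <- read.delim(file.path(dir, "specificity_weights.tsv"),
                     colClasses = "character")
    panel <- new("ReferencePanel", genes = genes, cellTypes = types,
                 mu = mu, var = vv, dispersion = lam, successProb = pp,
                 fitFlag = ff,
                 specificityWeight = as.numeric(sw$w_s),
                 geneMode = meta$gene_mode,
                 metadata = meta[setdiff(names(meta),
                     c("gene_mode", "n_genes", "cell_types"))])
    validObject(panel)
    panel
}

#' Write estimated proportions as TSV
#'
#' One row per sample: sample_id, one column per cell type (6 decimals),
#' plus converged and loss.
#'
#' @param result a [DeconvolutionResult-class].
#' @param path output file.
#' @export
writeProportions <- function(result, path) {
    th <- proportions(result)
    df <- data.frame(sample_id = rownames(th),
                     matrix(sprintf("%.6f", th), nrow(th), ncol(th)),
                     converged = result@converged,
                     loss = sprintf("%.6g", result@lossValue),
                     check.names = FALSE)
    colnames(df)[2:(1 + ncol(th))] <- colnames(th)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @importFrom tools file_ext
NULL
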