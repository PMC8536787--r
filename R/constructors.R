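#' Construct a single-cell reference
#'
#' @param counts genes x cells matrix (dense or sparse) of raw UMI counts;
#'   rownames are gene ids, colnames cell ids.
#' @param cellType character/factor of length \code{ncol(counts)}.
#' @param subject optional character/factor of subject (replicate) labels.
#' @return A [ScReference-class] object.
#' @examples
#' cnt <- matrix(rpois(20, 3), 4, 5,
#'               dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' ref <- ScReference(cnt, cellType = c("A", "A", "B", "B", "B"))
#' @export
ScReference <- function(counts, cellType, subject = NULL) {
    if (is.null(rownames(counts)))
        stop("counts must have gene ids as rownames")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
    if (length(cellType) != ncol(counts))
        stop("cellType must have one label per cell")
    cd <- S4Vectors::DataFrame(cellType = as.character(cellType),
                               row.names = colnames(counts))
    if (!is.null(subject)) {
        if (length(subject) != ncol(counts))
            stop("subject must have one label per cell")
        cd$subject <- as.character(subject)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("ScReference", se)
}

#' Construct a compound sample set
#'
#' @param counts genes x samples matrix of non-negative values (raw bulk
#'   counts or spot UMIs; reals allowed for simulated spots).
#' @param groups optional replicate-group label per sample; samples in the
#'   same group share the coarse estimate and correction factors during
#'   deconvolution.
#' @return A [CompoundSamples-class] object.
#' @export
CompoundSamples <- function(counts, groups = NULL) {
    if (is.null(rownames(counts)))
        stop("counts must have gene ids as rownames")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(groups)) {
        if (length(groups) != ncol(counts))
            stop("groups must have one label per sample")
        cd$group <- as.character(groups)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("CompoundSamples", se)
}
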