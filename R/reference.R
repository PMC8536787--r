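#' Select marker genes by one-vs-rest rank-sum enrichment
#'
#' For every cell type, genes are compared against all remaining cells with
#' a Wilcoxon rank-sum test on log1p counts-per-10k values (normalization is
#' used for testing only; the NB profile fits always act on raw UMIs).
#' Per type, genes with a Benjamini-Hochberg adjusted p-value below
#' \code{pCutoff} and positive enrichment are ranked by log2 fold change of
#' the type mean over the rest mean, and the top \code{topN} are kept. The
#' returned set is the union of the per-type lists, after removing genes
#' that appear in the lists of more than \code{maxTypes} types (insufficient
#' specificity) and mitochondrial genes.
#'
#' @param ref a [ScReference-class].
#' @param topN markers kept per cell type (default 200).
#' @param pCutoff BH-adjusted p-value cutoff (default 0.01).
#' @param maxTypes maximum number of per-type lists a gene may appear in
#'   (default 5).
#' @param mitoPrefixes gene-id prefixes treated as mitochondrial.
#' @return Character vector of gene ids, sorted.
#' @export
selectMarkerGenes <- function(ref, topN = 200, pCutoff = 0.01,
                              maxTypes = 5,
                              mitoPrefixes = c("mt-", "MT-", "Mt-")) {
    types <- unique(cellTypes(ref))
    if (length(types) < 2)
        stop("marker selection requires at least 2 cell types")
    norm <- logNormalize(counts(ref))
    labels <- cellTypes(ref)
    perType <- lapply(types, function(k) {
        inK <- labels == k
        p <- rankSumOneVsRest(norm, inK)
        padj <- p.adjust(p, method = "BH")
        mIn <- rowMeans(norm[, inK, drop = FALSE])
        mOut <- rowMeans(norm[, !inK, drop = FALSE])
        lfc <- log2((expm1(mIn) + 1) / (expm1(mOut) + 1))
        keep <- which(padj < pCutoff & lfc > 0)
        if (!length(keep)) return(character())
        ord <- keep[order(-lfc[keep], rownames(norm)[keep])]
        rownames(norm)[head(ord, topN)]
    })
    all <- unlist(perType)
    nLists <- table(all)
    promiscuous <- names(nLists)[nLists > maxTypes]
    sel <- setdiff(unique(all), promiscuous)
    sel <- sel[!isMito(sel, mitoPrefixes)]
    if (!length(sel))
        stop("no informative genes survived the marker filters")
    sort(sel)
}

#' Select highly variable genes on a cluster-balanced matrix
#'
#' Cell clusters are first balanced to the median cluster size (subsampled
#' without replacement when larger, upsampled with replacement when
#' smaller) so that large clusters do not dominate the variance ranking.
#' A variance-stabilizing standardization is then applied: a loess fit of
#' log10 variance on log10 mean predicts each gene's expected standard
#' deviation, cells are standardized by it and clipped at sqrt(N), and
#' genes are ranked by the variance of the clipped standardized values.
#'
#' @param ref a [ScReference-class].
#' @param nTop number of genes to return (default 2000; capped at the gene
#'   count with a warning).
#' @param seed integer seed controlling the balancing subsample.
#' @param mitoPrefixes gene-id prefixes treated as mitochondrial.
#' @param loessSpan span of the mean-variance trend fit.
#' @return Character vector of gene ids, ordered by decreasing
#'   standardized variance.
#' @export
selectBalancedHVGs <- function(ref, nTop = 2000, seed = 1,
                               mitoPrefixes = c("mt-", "MT-", "Mt-"),
                               loessSpan = 0.3) {
    labels <- cellTypes(ref)
    sizes <- table(labels)
    med <- round(median(sizes))
    cnt <- asDense(counts(ref))
    idx <- withSeed(seed, {
        unlist(lapply(names(sizes), function(k) {
            cells <- which(labels == k)
            if (length(cells) == med) cells
            else if (length(cells) > med) sample(cells, med)
            else sample(cells, med, replace = TRUE)
        }))
    })
    bal <- cnt[, idx, drop = FALSE]
    sv <- vstStandardizedVariance(bal, loessSpan)
    keep <- !isMito(rownames(bal), mitoPrefixes)
    ord <- order(-sv, rownames(bal))
    ord <- ord[keep[ord]]
    if (nTop > length(ord)) {
        warning(sprintf(
            "nTop = %d exceeds the %d available genes; capped", nTop,
            length(ord)))
        nTop <- length(ord)
    }
    rownames(bal)[ord[seq_len(nTop)]]
}

# standardized variance after a loess fit of log10(var) ~ log10(mean);
# standardized values clipped at sqrt(N)
vstStandardizedVariance <- function(mat, span = 0.3) {
    mu <- rowMeans(mat)
    vv <- apply(mat, 1, var)
    sv <- numeric(nrow(mat))
    use <- vv > 0 & mu > 0
    if (sum(use) >= 4) {
        fit <- loess(log10(vv[use]) ~ log10(mu[use]), span = span,
                     degree = 2)
        esd <- sqrt(10^predict(fit))
        clipMax <- sqrt(ncol(mat))
        z <- (mat[use, , drop = FALSE] - mu[use]) / esd
        z[z > clipMax] <- clipMax
        z[z < -clipMax] <- -clipMax
        sv[use] <- apply(z, 1, var)
    } else if (any(use)) {
        sv[use] <- vv[use] / mu[use]
    }
    names(sv) <- rownames(mat)
    sv
}

#' Cell-type specificity weights of a fitted panel
#'
#' For each gene the most-expressing cell type
#' \eqn{k' = \arg\max_k \mu_{ik}} is found (ties broken by the lowest
#' cell-type index, with a message) and the weight is the mean-to-variance
#' ratio in that type, \eqn{w^S_i = \mu_{ik'} / \sigma^2_{ik'}}. Under the
#' NB parametrization this equals \eqn{1 - \hat p_{ik'}}, so weights lie in
#' (0, 1]; Poisson-fallback genes get exactly 1. Genes whose best type is
#' an all-zero fit are uninformative and returned as NA (dropped by
#' [buildReference()]).
#'
#' @param panel a [ReferencePanel-class] (possibly with unset weights).
#' @return Named numeric vector of weights, NA for all-zero genes.
#' @export
computeSpecificityWeights <- function(panel) {
    mu <- panel@mu; vv <- panel@var; fl <- panel@fitFlag
    w <- vapply(seq_along(panel@genes), function(i) {
        best <- which(mu[i, ] == max(mu[i, ]))
        if (length(best) > 1)
            message(sprintf(
                "gene %s: argmax tie over cell types (%s); using the first",
                panel@genes[i],
                paste(panel@cellTypes[best], collapse = ", ")))
        kp <- best[1]
        if (fl[i, kp] == "all_zero") return(NA_real_)
        mu[i, kp] / vv[i, kp]
    }, numeric(1))
    setNames(w, panel@genes)
}

#' Build a reference panel from annotated single cells
#'
#' Orchestrates gene selection, per-(gene, cell type) negative-binomial
#' profile fits on raw UMI counts, and specificity weighting. The result is
#' independent of the order of cells within a type and, for a fixed seed,
#' fully deterministic.
#'
#' @param ref a [ScReference-class].
#' @param geneMode \code{"marker"} (one-vs-rest enrichment,
#'   [selectMarkerGenes()]) or \code{"hvg"} (balanced highly variable
#'   genes, [selectBalancedHVGs()]).
#' @param genes optional explicit gene set, bypassing selection
#'   (\code{geneMode} recorded as \code{"custom"}).
#' @param minCellsPerType minimum cells required per type (default 10).
#' @param seed seed for the HVG balancing subsample.
#' @param ... passed to the gene-selection function.
#' @return A [ReferencePanel-class].
#' @export
buildReference <- function(ref, geneMode = c("marker", "hvg"),
                           genes = NULL, minCellsPerType = 10, seed = 1,
                           ...) {
    labels <- cellTypes(ref)
    sizes <- table(labels)
    if (any(sizes < minCellsPerType))
        stop(sprintf("cell types below %d cells: %s", minCellsPerType,
                     paste(names(sizes)[sizes < minCellsPerType],
                           collapse = ", ")))
    if (is.null(genes)) {
        geneMode <- match.arg(geneMode)
        genes <- switch(geneMode,
            marker = selectMarkerGenes(ref, ...),
            hvg = selectBalancedHVGs(ref, seed = seed, ...))
    } else {
        missing <- setdiff(genes, rownames(ref))
        if (length(missing))
            stop("unknown genes requested: ",
                 paste(head(missing, 5), collapse = ", "))
        geneMode <- "custom"
    }
    types <- sort(unique(labels))
    cnt <- asDense(counts(ref))[genes, , drop = FALSE]
    I <- length(genes); K <- length(types)
    mu <- vv <- lam <- pp <- matrix(NA_real_, I, K,
                                    dimnames = list(genes, types))
    fl <- matrix(NA_character_, I, K, dimnames = list(genes, types))
    for (k in seq_len(K)) {
        cells <- which(labels == types[k])
        sub <- cnt[, cells, drop = FALSE]
        for (i in seq_len(I)) {
            f <- fitNbProfile(sub[i, ])
            mu[i, k] <- f$mu; vv[i, k] <- f$var
            lam[i, k] <- if (is.na(f$lambda)) f$mu else f$lambda
            pp[i, k] <- if (is.na(f$p)) 0 else f$p
            fl[i, k] <- f$flag
        }
    }
    panel <- new("ReferencePanel", genes = genes, cellTypes = types,
                 mu = mu, var = vv, dispersion = lam, successProb = pp,
                 fitFlag = fl,
                 specificityWeight = rep(1, I), geneMode = geneMode,
                 metadata = list(schema_version = .BUNDLE_SCHEMA_VERSION,
                                 n_cells = ncol(ref), seed = seed,
                                 params = list(...)))
    w <- suppressMessages(computeSpecificityWeights(panel))
    if (anyNA(w)) {
        warning(sprintf("dropping %d genes with all-zero best cell type",
                        sum(is.na(w))))
        keep <- which(!is.na(w))
        panel <- subsetPanel(panel, keep)
        w <- w[keep]
    }
    panel@specificityWeight <- unname(w)
    validObject(panel)
    panel
}

subsetPanel <- function(panel, idx) {
    new("ReferencePanel",
        genes = panel@genes[idx],
        cellTypes = panel@cellTypes,
        mu = panel@mu[idx, , drop = FALSE],
        var = panel@var[idx, , drop = FALSE],
        dispersion = panel@dispersion[idx, , drop = FALSE],
        successProb = panel@successProb[idx, , drop = FALSE],
        fitFlag = panel@fitFlag[idx, , drop = FALSE],
        specificityWeight = panel@specificityWeight[idx],
        geneMode = panel@geneMode,
        metadata = panel@metadata)
}
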