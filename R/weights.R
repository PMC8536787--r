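#' Cross-sample variability weights
#'
#' Quantifies how stable each gene is across samples via the
#' variance-to-mean ratio (VMR) of a negative-binomial fit across samples:
#' \eqn{VMR_i = (\sigma_i^2)^S / \mu_i^S = 1 / (1 - \hat p)} and the
#' stability weight \eqn{w^C_i = 1 / VMR_i}. Three availability modes are
#' supported, mirroring what data are at hand:
#' \describe{
#'   \item{compound_replicates}{the compound matrix itself has >= 3
#'     replicate samples; the fit runs across its columns (per replicate
#'     group when \code{groups} is given, group VMRs combined by a
#'     size-weighted mean).}
#'   \item{reference_replicates}{the single-cell reference has >= 3
#'     subjects; one pseudo-sample per subject is synthesized by summing
#'     raw UMIs over all of the subject's cells.}
#'   \item{bootstrap}{no replicates anywhere; \code{B} pseudo-samples are
#'     built by resampling cells with replacement per cell type at the
#'     original cluster sizes and pooling them.}
#' }
#' Poisson-fallback genes get VMR = 1 and \eqn{w^C = 1}; genes with all-zero
#' cross-sample counts get \eqn{w^C = 0} and are excluded from the loss.
#' Weights are clipped at \code{wCeiling}.
#'
#' @param x a genes x samples matrix (or [CompoundSamples-class]) for
#'   \code{compound_replicates}; a [ScReference-class] for the other modes.
#' @param mode one of \code{"compound_replicates"},
#'   \code{"reference_replicates"}, \code{"bootstrap"}.
#' @param B number of bootstrap pseudo-samples (default 20).
#' @param seed bootstrap seed.
#' @param wCeiling upper clip for the weights (default 10).
#' @param groups optional replicate-group labels (compound mode).
#' @param genes optional gene subset to compute weights for (defaults to
#'   all rows).
#' @return A [CrossSampleWeights-class].
#' @export
computeCrossSampleWeights <- function(x,
        mode = c("compound_replicates", "reference_replicates", "bootstrap"),
        B = 20, seed = 1, wCeiling = 10, groups = NULL, genes = NULL) {
    mode <- match.arg(mode)
    if (mode == "compound_replicates") {
        if (is(x, "CompoundSamples")) {
            if (is.null(groups)) groups <- sampleGroups(x)
            x <- counts(x)
        }
        x <- asDense(x)
        if (!is.null(genes)) x <- x[genes, , drop = FALSE]
        if (is.null(groups)) groups <- rep("all", ncol(x))
        sizes <- table(groups)
        if (any(sizes < 3))
            stop("mode 'compound_replicates' requires >= 3 samples per ",
                 "replicate group (smallest group has ", min(sizes), ")")
        perGroup <- lapply(unique(groups), function(g)
            vmrPerGene(round(x[, groups == g, drop = FALSE])))
        wts <- as.numeric(sizes[unique(groups)])
        vmrMat <- do.call(cbind, lapply(perGroup, `[[`, "vmr"))
        vmrs <- as.vector(vmrMat %*% (wts / sum(wts)))
        # a gene unexpressed in every group stays excluded
        allZero <- Reduce(`&`, lapply(perGroup, function(p)
            p$flag == "all_zero"))
        flag <- perGroup[[1]]$flag
        flag[allZero] <- "all_zero"
        res <- list(vmr = vmrs, flag = flag)
        res$vmr[allZero] <- 0
        geneIds <- rownames(x)
        B <- NA_integer_; seed <- NA_integer_
    } else if (mode == "reference_replicates") {
        stopifnot(is(x, "ScReference"))
        subj <- subjects(x)
        if (is.null(subj) || length(unique(subj)) < 3)
            stop("mode 'reference_replicates' requires >= 3 subjects in ",
                 "the reference")
        cnt <- asDense(counts(x))
        if (!is.null(genes)) cnt <- cnt[genes, , drop = FALSE]
        pseudo <- vapply(unique(subj), function(s)
            rowSums(cnt[, subj == s, drop = FALSE]),
            numeric(nrow(cnt)))
        res <- vmrPerGene(pseudo)
        geneIds <- rownames(cnt)
        B <- NA_integer_; seed <- NA_integer_
    } else {
        stopifnot(is(x, "ScReference"))
        if (B < 3) stop("mode 'bootstrap' requires B >= 3")
        labels <- cellTypes(x)
        cnt <- asDense(counts(x))
        if (!is.null(genes)) cnt <- cnt[genes, , drop = FALSE]
        typeIdx <- split(seq_along(labels), labels)
        pseudo <- withSeed(seed, {
            vapply(seq_len(B), function(b) {
                take <- unlist(lapply(typeIdx, function(ix)
                    sample(ix, length(ix), replace = TRUE)))
                rowSums(cnt[, take, drop = FALSE])
            }, numeric(nrow(cnt)))
        })
        res <- vmrPerGene(pseudo)
        geneIds <- rownames(cnt)
        B <- as.integer(B); seed <- as.integer(seed)
    }
    wC <- ifelse(res$vmr > 0, pmin(1 / res$vmr, wCeiling), 0)
    new("CrossSampleWeights", genes = geneIds, vmr = res$vmr, wC = wC,
        mode = mode, fitFlag = res$flag, B = B, seed = seed)
}

# per-gene NB fit across the columns of `mat`; VMR = 1/(1-p) for nb_ok,
# 1 for poisson_fallback, 0 for all-zero genes
vmrPerGene <- function(mat) {
    vmr <- numeric(nrow(mat))
    flag <- character(nrow(mat))
    for (i in seq_len(nrow(mat))) {
        f <- fitNbProfile(round(mat[i, ]))
        flag[i] <- f$flag
        vmr[i] <- switch(f$flag,
            all_zero = 0,
            poisson_fallback = 1,
            nb_ok = f$var / f$mu)
    }
    list(vmr = vmr, flag = flag)
}

#' Write cross-sample weights to a TSV file
#'
#' Columns: gene_id, vmr, w_c, mode.
#' @param weights a [CrossSampleWeights-class].
#' @param path output file.
#' @export
writeCrossSampleWeights <- function(weights, path) {
    df <- data.frame(gene_id = weights@genes,
                     vmr = sprintf("%.17g", weights@vmr),
                     w_c = sprintf("%.17g", weights@wC),
                     mode = weights@mode)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
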