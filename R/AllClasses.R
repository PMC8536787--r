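#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats optim var median mad loess predict p.adjust pnorm cor
#'   rnorm runif rnbinom rgamma setNames quantile
#' @importFrom utils read.delim write.table head
NULL

.FIT_FLAGS <- c("nb_ok", "poisson_fallback", "all_zero")
.BUNDLE_SCHEMA_VERSION <- "1.0"

#' Annotated single-cell reference counts
#'
#' Container for a raw UMI count matrix (genes x cells) with a cell-type
#' label per cell and an optional subject (biological replicate) label.
#' Counts are kept raw throughout: the negative-binomial profile fits act
#' on un-normalized UMIs so that cell-type differences in total transcript
#' content are preserved.
#'
#' @slot ... inherits from \linkS4class{SummarizedExperiment}; the
#'   \code{counts} assay holds the UMI matrix, \code{colData} carries
#'   \code{cellType} and optionally \code{subject}.
#'
#' @seealso [ScReference()] for construction, [buildReference()] to fit a
#'   [ReferencePanel-class].
#' @export
setClass("ScReference", contains = "SummarizedExperiment")

setValidity("ScReference", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        x <- SummarizedExperiment::assay(object, "counts")
        if (min0(x) < 0) msg <- c(msg, "counts must be non-negative")
        if (!allIntegral(x)) msg <- c(msg, "counts must be integral UMIs")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (!"cellType" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData column 'cellType' is required")
    if (length(msg)) msg else TRUE
})

#' Compound (bulk or spatial) samples to deconvolute
#'
#' Genes x samples matrix of non-negative values. Real-valued entries are
#' permitted because simulated spatial spots are weighted sums of cells.
#' An optional \code{group} column in \code{colData} marks replicate
#' groups that share a coarse estimate and correction factors.
#'
#' @seealso [CompoundSamples()], [deconvolute()]
#' @export
setClass("CompoundSamples", contains = "SummarizedExperiment")

setValidity("CompoundSamples", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else if (min0(SummarizedExperiment::assay(object, "counts")) < 0)
        msg <- c(msg, "counts must be non-negative")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Fitted reference panel of per-gene, per-cell-type NB profiles
#'
#' Holds, for each selected gene and each cell type, the maximum-likelihood
#' negative-binomial parameters (dispersion \eqn{\lambda}, success
#' probability \eqn{p}) together with the implied mean
#' \eqn{\mu = \lambda p / (1 - p)} and variance
#' \eqn{\sigma^2 = \lambda p / (1 - p)^2}, a per-fit flag, and the
#' per-gene cell-type-specificity weight \eqn{w^S_i =
#' \mu_{ik'} / \sigma^2_{ik'}} where \eqn{k'} is the most-expressing type.
#'
#' @slot genes character, selected gene ids (ordered).
#' @slot cellTypes character, cell-type names (columns of the matrices).
#' @slot mu,var,dispersion,successProb numeric I x K matrices.
#' @slot fitFlag character I x K matrix with values
#'   \code{nb_ok}, \code{poisson_fallback} or \code{all_zero}.
#' @slot specificityWeight numeric length-I vector in (0, 1].
#' @slot geneMode \code{"marker"} or \code{"hvg"}.
#' @slot metadata list of provenance (parameters, seed, source hash,
#'   schema version).
#' @export
setClass("ReferencePanel",
    representation(
        genes = "character",
        cellTypes = "character",
        mu = "matrix",
        var = "matrix",
        dispersion = "matrix",
        successProb = "matrix",
        fitFlag = "matrix",
        specificityWeight = "numeric",
        geneMode = "character",
        metadata = "list"
    )
)

setValidity("ReferencePanel", function(object) {
    msg <- character()
    I <- length(object@genes); K <- length(object@cellTypes)
    for (s in c("mu", "var", "dispersion", "successProb", "fitFlag")) {
        m <- slot(object, s)
        if (!identical(dim(m), c(I, K)))
            msg <- c(msg, sprintf("slot '%s' must be %d x %d", s, I, K))
    }
    if (length(object@specificityWeight) != I)
        msg <- c(msg, "specificityWeight must have one entry per gene")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene ids must be unique")
    if (!all(object@fitFlag %in% .FIT_FLAGS))
        msg <- c(msg, "fitFlag entries must be nb_ok/poisson_fallback/all_zero")
    if (!object@geneMode %in% c("marker", "hvg", "custom"))
        msg <- c(msg, "geneMode must be 'marker', 'hvg' or 'custom'")
    if (length(msg)) return(msg)
    ok <- object@fitFlag == "nb_ok"
    if (any(ok)) {
        if (any(object@var[ok] <= object@mu[ok]))
            msg <- c(msg, "nb_ok fits must be overdispersed (var > mu)")
        muImplied <- object@dispersion[ok] * object@successProb[ok] /
            (1 - object@successProb[ok])
        if (any(abs(muImplied - object@mu[ok]) >
                1e-6 * pmax(1, abs(object@mu[ok]))))
            msg <- c(msg, "nb_ok fits must satisfy mu = lambda*p/(1-p)")
        if (any(object@successProb[ok] < 0 | object@successProb[ok] >= 1))
            msg <- c(msg, "success probabilities must lie in [0, 1)")
    }
    pf <- object@fitFlag == "poisson_fallback"
    if (any(pf) && any(abs(object@var[pf] - object@mu[pf]) > 1e-8))
        msg <- c(msg, "poisson_fallback fits must have var == mu")
    az <- object@fitFlag == "all_zero"
    if (any(az) && any(object@mu[az] != 0 | object@var[az] != 0))
        msg <- c(msg, "all_zero fits must have mu == var == 0")
    w <- object@specificityWeight
    if (length(w) && (any(!is.finite(w)) || any(w <= 0 | w > 1 + 1e-9)))
        msg <- c(msg, "specificity weights must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Per-gene cross-sample variability weights
#'
#' The variance-to-mean ratio (VMR) of each gene across compound samples
#' (or pseudo-samples synthesized from the single-cell reference), and its
#' reciprocal, the stability weight \eqn{w^C_i = 1 / VMR_i}. Genes whose
#' cross-sample counts are all zero get \eqn{w^C = 0} and are excluded from
#' the deconvolution loss.
#'
#' @slot genes character gene ids.
#' @slot vmr,wC numeric vectors aligned to \code{genes}.
#' @slot mode one of \code{compound_replicates}, \code{reference_replicates},
#'   \code{bootstrap}.
#' @slot fitFlag character per-gene NB fit flag.
#' @slot B,seed bootstrap settings when \code{mode == "bootstrap"}.
#' @export
setClass("CrossSampleWeights",
    representation(
        genes = "character",
        vmr = "numeric",
        wC = "numeric",
        mode = "character",
        fitFlag = "character",
        B = "integer",
        seed = "integer"
    )
)

setValidity("CrossSampleWeights", function(object) {
    msg <- character()
    I <- length(object@genes)
    if (length(object@vmr) != I || length(object@wC) != I ||
        length(object@fitFlag) != I)
        msg <- c(msg, "vmr, wC and fitFlag must align with genes")
    if (!object@mode %in% c("compound_replicates", "reference_replicates",
                            "bootstrap"))
        msg <- c(msg, "unknown mode")
    if (any(object@vmr < 0) || any(object@wC < 0))
        msg <- c(msg, "vmr and wC must be non-negative")
    pos <- object@vmr > 0 & object@wC > 0
    # clipping caps wC below 1/VMR, so require wC * VMR <= 1 + tol and
    # equality wherever no clipping occurred (wC < ceiling is not stored;
    # accept either exact identity or a capped value)
    if (any(object@wC[pos] * object@vmr[pos] > 1 + 1e-8))
        msg <- c(msg, "wC must not exceed 1/VMR")
    if (length(msg)) msg else TRUE
})

#' Deconvolution result for a set of compound samples
#'
#' @slot theta samples x cell-types matrix of proportions; every row is
#'   non-negative and sums to one.
#' @slot betaRaw samples x cell-types matrix of raw coefficients before
#'   rescaling.
#' @slot tauCoarse samples x cell-types matrix, the coarse NNLS estimate
#'   of the sample's replicate group.
#' @slot correctionFactors genes x groups matrix of gene-wise platform
#'   corrections r (NA where a gene was excluded from the loss).
#' @slot sampleGroups character, replicate group of each sample.
#' @slot lossValue,nIter numeric per sample.
#' @slot converged logical per sample.
#' @slot lambdaUsed numeric per sample.
#' @slot genes character, genes used in the loss.
#' @export
setClass("DeconvolutionResult",
    representation(
        theta = "matrix",
        betaRaw = "matrix",
        tauCoarse = "matrix",
        correctionFactors = "matrix",
        sampleGroups = "character",
        lossValue = "numeric",
        nIter = "numeric",
        converged = "logical",
        lambdaUsed = "numeric",
        genes = "character"
    )
)

setValidity("DeconvolutionResult", function(object) {
    msg <- character()
    th <- object@theta
    if (nrow(th) && (any(th < -1e-12) ||
        any(abs(rowSums(th) - 1) > 1e-9)))
        msg <- c(msg, "theta rows must be non-negative and sum to 1")
    if (!identical(dim(th), dim(object@betaRaw)))
        msg <- c(msg, "betaRaw must match theta's dimensions")
    if (length(msg)) msg else TRUE
})

#' Ground-truth mixing proportions of a synthesized sample
#'
#' @slot theta0 named numeric vector on the simplex.
#' @slot provenance \code{"cell_counts"} (truth derived from the number of
#'   pooled cells per type) or \code{"scheme"} (named proportion scheme).
#' @slot schemeId optional scheme label (e.g. \code{"mix0"}).
#' @slot schemeAsPrinted optional un-normalized proportions as supplied.
#' @slot seed integer seed used for sampling, \code{NA} if none.
#' @export
setClass("MixingTruth",
    representation(
        theta0 = "numeric",
        provenance = "character",
        schemeId = "character",
        schemeAsPrinted = "numeric",
        seed = "integer"
    ),
    prototype(schemeId = NA_character_, schemeAsPrinted = numeric(),
              seed = NA_integer_)
)

setValidity("MixingTruth", function(object) {
    msg <- character()
    if (any(object@theta0 < 0) || abs(sum(object@theta0) - 1) > 1e-12)
        msg <- c(msg, "theta0 must be on the simplex (sum 1 within 1e-12)")
    if (!object@provenance %in% c("cell_counts", "scheme"))
        msg <- c(msg, "provenance must be 'cell_counts' or 'scheme'")
    if (length(msg)) msg else TRUE
})

#' Evaluation report
#'
#' Concordance of estimated against true proportions, with optional ROC
#' and detection-rate components.
#'
#' @slot perSample data.frame of per-sample (or per-subject) metrics.
#' @slot pooled named numeric of pooled metrics.
#' @slot roc data.frame with columns threshold, fpr, tpr (may be empty).
#' @slot auc numeric, NA when no ROC was computed.
#' @slot detection data.frame of detection rates (may be empty).
#' @slot details list of extra payloads (estimates, truths, seeds).
#' @export
setClass("EvaluationReport",
    representation(
        perSample = "data.frame",
        pooled = "numeric",
        roc = "data.frame",
        auc = "numeric",
        detection = "data.frame",
        details = "list"
    ),
    prototype(roc = data.frame(), auc = NA_real_,
              detection = data.frame(), details = list())
)
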