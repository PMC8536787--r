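#' @importFrom BiocGenerics counts
NULL

#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param x,object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "ScReference", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setMethod("counts", "CompoundSamples", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setMethod("cellTypes", "ScReference", function(x)
    SummarizedExperiment::colData(x)$cellType)

#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setMethod("subjects", "ScReference", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("subject" %in% colnames(cd)) cd$subject else NULL
})

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "CompoundSamples", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("group" %in% colnames(cd)) cd$group else NULL
})

#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname accessors
#' @export
setMethod("selectedGenes", "ReferencePanel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("cellTypeNames", function(x) standardGeneric("cellTypeNames"))

#' @rdname accessors
#' @export
setMethod("cellTypeNames", "ReferencePanel", function(x) x@cellTypes)

#' @rdname accessors
#' @export
setGeneric("nbMeans", function(x) standardGeneric("nbMeans"))

#' @rdname accessors
#' @export
setMethod("nbMeans", "ReferencePanel", function(x) x@mu)

#' @rdname accessors
#' @export
setGeneric("nbVariances", function(x) standardGeneric("nbVariances"))

#' @rdname accessors
#' @export
setMethod("nbVariances", "ReferencePanel", function(x) x@var)

#' @rdname accessors
#' @export
setGeneric("nbDispersions", function(x) standardGeneric("nbDispersions"))

#' @rdname accessors
#' @export
setMethod("nbDispersions", "ReferencePanel", function(x) x@dispersion)

#' @rdname accessors
#' @export
setGeneric("nbSuccessProbs", function(x) standardGeneric("nbSuccessProbs"))

#' @rdname accessors
#' @export
setMethod("nbSuccessProbs", "ReferencePanel", function(x) x@successProb)

#' @rdname accessors
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))

#' @rdname accessors
#' @export
setMethod("fitFlags", "ReferencePanel", function(x) x@fitFlag)

#' @rdname accessors
#' @export
setMethod("fitFlags", "CrossSampleWeights", function(x)
    setNames(x@fitFlag, x@genes))

#' @rdname accessors
#' @export
setGeneric("specificityWeights", function(x)
    standardGeneric("specificityWeights"))

#' @rdname accessors
#' @export
setMethod("specificityWeights", "ReferencePanel", function(x)
    setNames(x@specificityWeight, x@genes))

#' @rdname accessors
#' @export
setGeneric("geneMode", function(x) standardGeneric("geneMode"))

#' @rdname accessors
#' @export
setMethod("geneMode", "ReferencePanel", function(x) x@geneMode)

#' @rdname accessors
#' @export
setGeneric("vmr", function(x) standardGeneric("vmr"))

#' @rdname accessors
#' @export
setMethod("vmr", "CrossSampleWeights", function(x) setNames(x@vmr, x@genes))

#' @rdname accessors
#' @export
setGeneric("stabilityWeights", function(x)
    standardGeneric("stabilityWeights"))

#' @rdname accessors
#' @export
setMethod("stabilityWeights", "CrossSampleWeights", function(x)
    setNames(x@wC, x@genes))

#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname accessors
#' @export
setMethod("proportions", "DeconvolutionResult", function(x) x@theta)

#' @rdname accessors
#' @export
setMethod("proportions", "MixingTruth", function(x) x@theta0)

#' @rdname accessors
#' @export
setGeneric("rawCoefficients", function(x) standardGeneric("rawCoefficients"))

#' @rdname accessors
#' @export
setMethod("rawCoefficients", "DeconvolutionResult", function(x) x@betaRaw)

#' @rdname accessors
#' @export
setGeneric("coarseProportions", function(x)
    standardGeneric("coarseProportions"))

#' @rdname accessors
#' @export
setMethod("coarseProportions", "DeconvolutionResult", function(x)
    x@tauCoarse)

#' @rdname accessors
#' @export
setGeneric("correctionFactors", function(x)
    standardGeneric("correctionFactors"))

#' @rdname accessors
#' @export
setMethod("correctionFactors", "DeconvolutionResult", function(x)
    x@correctionFactors)

#' @rdname accessors
#' @export
setGeneric("convergenceInfo", function(x) standardGeneric("convergenceInfo"))

#' @rdname accessors
#' @export
setMethod("convergenceInfo", "DeconvolutionResult", function(x)
    data.frame(sample = rownames(x@theta), converged = x@converged,
               loss = x@lossValue, nIter = x@nIter,
               lambda = x@lambdaUsed, row.names = NULL))

# ---- show methods -----------------------------------------------------

setMethod("show", "ReferencePanel", function(object) {
    cat("ReferencePanel:", length(object@genes), "genes x",
        length(object@cellTypes), "cell types\n")
    cat("  gene mode:", object@geneMode, "\n")
    tab <- table(factor(object@fitFlag, levels = .FIT_FLAGS))
    cat("  fits:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  cell types:", paste(head(object@cellTypes, 8), collapse = ", "),
        if (length(object@cellTypes) > 8) "..." else "", "\n")
})

setMethod("show", "CrossSampleWeights", function(object) {
    cat("CrossSampleWeights:", length(object@genes), "genes, mode =",
        object@mode, "\n")
    cat(sprintf("  VMR median %.3g; w^C in [%.3g, %.3g]; %d excluded\n",
                median(object@vmr[object@wC > 0]),
                min(object@wC), max(object@wC), sum(object@wC == 0)))
})

setMethod("show", "DeconvolutionResult", function(object) {
    cat("DeconvolutionResult:", nrow(object@theta), "samples x",
        ncol(object@theta), "cell types;",
        sum(object@converged), "converged\n")
    print(head(round(object@theta, 4), 5))
    if (nrow(object@theta) > 5) cat("  ...\n")
})

setMethod("show", "MixingTruth", function(object) {
    cat("MixingTruth (", object@provenance, "):\n", sep = "")
    print(round(object@theta0, 4))
})

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    if (nrow(object@perSample)) {
        cat(" per-sample metrics (first rows):\n")
        print(head(object@perSample, 5))
    }
    if (length(object@pooled)) {
        cat(" pooled:\n")
        print(round(object@pooled, 4))
    }
    if (!is.na(object@auc)) cat(" AUC:", round(object@auc, 4), "\n")
})
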